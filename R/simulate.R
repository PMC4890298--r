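#' Tile a genome into consecutive bins
#'
#' Produces consecutive half-open bins of a fixed width along each
#' chromosome, truncating the last bin at the chromosome end. Useful as
#' the row/column grid for [inflate()].
#'
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param bin_width Bin width in bp, >= 1.
#' @return Region data frame in canonical order.
#' @examples
#' tile_genome(c(chr1 = 1000, chr2 = 500), 300)
#' @export
tile_genome <- function(genome, bin_width) {
  genome <- check_genome(genome)
  if (length(bin_width) != 1L || is.na(bin_width) || bin_width < 1) {
    stop("bin_width must be a single integer >= 1", call. = FALSE)
  }
  chroms <- sort(names(genome), method = "radix")
  parts <- lapply(chroms, function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, len - 1, by = bin_width)
    gregions(chr, starts, pmin(starts + bin_width, len))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

check_genome <- function(genome) {
  if (length(genome) == 0L || is.null(names(genome)) ||
      any(!nzchar(names(genome)))) {
    stop("genome must be a named vector of chromosome lengths",
         call. = FALSE)
  }
  if (any(is.na(genome)) || any(genome < 1)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  genome
}

#' Simulate a seeded interaction data set
#'
#' Generates a reproducible synthetic [AssaySet-class] for testing and
#' examples. Anchors are fixed-width windows placed uniformly on the
#' genome; each interaction is intra-chromosomal with probability
#' `intra_fraction`. A single `"counts"` assay holds negative-binomial
#' counts whose mean decays with genomic distance for cis pairs —
#' `mu = 10 * (1 + d/1000)^(-decay_exponent)` with `d` the mid-to-mid
#' distance in bp, so short-range pairs sit at the base mean of 10 — and
#' is a constant low 1 for trans pairs. The dispersion is fixed at 0.5
#' (`rnbinom` size 2). The same seed always yields the identical object;
#' the generator drives one private RNG stream and leaves the caller's
#' RNG state untouched.
#'
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param n Number of interactions.
#' @param m_samples Number of samples (assay columns).
#' @param seed Integer seed.
#' @param intra_fraction Probability that a pair is intra-chromosomal.
#' @param decay_exponent Positive decay exponent for the cis count mean.
#' @param anchor_width Anchor window width in bp.
#' @return An [AssaySet-class] with one `"counts"` assay and a
#'   `sample` column in its sample metadata.
#' @export
simulate_interaction_data <- function(genome = c(chr1 = 1e6, chr2 = 8e5,
                                                 chr3 = 5e5),
                                      n = 100, m_samples = 2, seed = 1,
                                      intra_fraction = 0.8,
                                      decay_exponent = 1,
                                      anchor_width = 1000) {
  genome <- check_genome(genome)
  if (any(genome <= anchor_width)) {
    stop("every chromosome must be longer than anchor_width", call. = FALSE)
  }
  if (is.na(intra_fraction) || intra_fraction < 0 || intra_fraction > 1) {
    stop("intra_fraction must be a probability in [0, 1]", call. = FALSE)
  }
  if (is.na(decay_exponent) || decay_exponent <= 0) {
    stop("decay_exponent must be positive", call. = FALSE)
  }
  n <- as.integer(n)
  m_samples <- as.integer(m_samples)
  if (n < 0L || m_samples < 0L) {
    stop("n and m_samples must be non-negative", call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  chroms <- names(genome)
  draw_anchor <- function(chr) {
    start <- floor(stats::runif(length(chr)) *
                     (genome[chr] - anchor_width + 1))
    gregions(chr, start, start + anchor_width)
  }
  chr1 <- sample(chroms, n, replace = TRUE, prob = genome / sum(genome))
  intra <- stats::runif(n) < intra_fraction
  chr2 <- chr1
  if (length(chroms) > 1L) {
    for (i in which(!intra)) {
      others <- setdiff(chroms, chr1[i])
      chr2[i] <- sample(others, 1L, prob = genome[others] / sum(genome[others]))
    }
  }
  a1 <- draw_anchor(chr1)
  a2 <- draw_anchor(chr2)
  tab <- make_interactions(a1, a2,
                           metadata = data.frame(name = sprintf("I%d", seq_len(max(n, 0L)))[seq_len(n)]),
                           global_metadata = list(seed = as.integer(seed)))

  d <- pair_distance(tab, "mid")
  mu <- ifelse(is.na(d), 1, 10 * (1 + d / 1000)^(-decay_exponent))
  counts <- matrix(stats::rnbinom(n * m_samples, mu = rep(mu, m_samples),
                                  size = 2),
                   nrow = n, ncol = m_samples)
  smd <- data.frame(sample = sprintf("S%d", seq_len(m_samples)))
  make_assay_set(tab,
                 assays = if (m_samples > 0L) list(counts = counts)
                          else list(),
                 sample_metadata = smd,
                 global_metadata = list(seed = as.integer(seed),
                                        decay_exponent = decay_exponent,
                                        intra_fraction = intra_fraction))
}
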