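#' Test overlap between genomic regions
#'
#' The primitive predicate behind every overlap method. Two regions
#' overlap when they share a chromosome and either their intersection is
#' at least `minoverlap` bases long, or (`minoverlap == 1` only) the gap
#' separating them is at most `maxgap` bases. Abutting half-open
#' intervals have a gap of 0, so with the defaults (`maxgap = 0`,
#' `minoverlap = 1`) book-ended regions count as overlapping. Strand is
#' ignored.
#'
#' @param a,b Region data frames; rows are recycled to a common length
#'   and compared elementwise.
#' @param maxgap Maximum separating gap (bp) still accepted, >= 0.
#' @param minoverlap Minimum intersection width (bp) required, >= 1.
#' @return Logical vector.
#' @examples
#' region_overlap(gregions("chr1", 100, 200), gregions("chr1", 200, 300))
#' @export
region_overlap <- function(a, b, maxgap = 0, minoverlap = 1) {
  a <- validate_regions(a)
  b <- validate_regions(b)
  check_overlap_args(maxgap, minoverlap)
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  overlap_predicate(a$chrom[idx_a], a$start[idx_a], a$end[idx_a],
                    b$chrom[idx_b], b$start[idx_b], b$end[idx_b],
                    maxgap, minoverlap)
}

check_overlap_args <- function(maxgap, minoverlap) {
  if (length(maxgap) != 1L || is.na(maxgap) || maxgap < 0) {
    stop("maxgap must be a single non-negative number", call. = FALSE)
  }
  if (length(minoverlap) != 1L || is.na(minoverlap) || minoverlap < 1) {
    stop("minoverlap must be a single number >= 1", call. = FALSE)
  }
}

# Vectorized core predicate on parallel coordinate vectors.
overlap_predicate <- function(c1, s1, e1, c2, s2, e2, maxgap, minoverlap) {
  inter <- pmin(e1, e2) - pmax(s1, s2)   # negative => disjoint, -inter = gap
  hit <- inter >= minoverlap
  if (minoverlap == 1) {
    hit <- hit | (-inter <= maxgap & inter <= 0)
  }
  hit & (c1 == c2)
}

# All overlapping (i, j) pairs between two region frames, restricted per
# chromosome to keep the cross product small. Returns a data.frame with
# integer columns i, j (unsorted).
overlap_pairs <- function(a, b, maxgap, minoverlap) {
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  res_i <- integer(0)
  res_j <- integer(0)
  for (chr in shared) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    grid_i <- rep(ia, times = length(ib))
    grid_j <- rep(ib, each = length(ia))
    keep <- overlap_predicate(chr, a$start[grid_i], a$end[grid_i],
                              chr, b$start[grid_j], b$end[grid_j],
                              maxgap, minoverlap)
    res_i <- c(res_i, grid_i[keep])
    res_j <- c(res_j, grid_j[keep])
  }
  data.frame(i = res_i, j = res_j)
}

sort_hits <- function(df) {
  ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' One-dimensional overlaps between interactions and regions
#'
#' An interaction has a one-dimensional overlap with a subject region
#' when either of its anchors overlaps that region. Use this to pull out
#' interactions touching pre-defined regions of interest.
#'
#' @param x An [InteractionTable-class].
#' @param subjects Region data frame of subject intervals.
#' @inheritParams region_overlap
#' @return data.frame with integer columns `query` (interaction index)
#'   and `subject`, sorted by (query, subject); each pair reported once
#'   even when both anchors hit the same subject.
#' @export
overlaps_any_region <- function(x, subjects, maxgap = 0, minoverlap = 1) {
  subjects <- validate_regions(subjects, what = "subject region")
  check_overlap_args(maxgap, minoverlap)
  a <- anchors(x)
  h1 <- overlap_pairs(a$first, subjects, maxgap, minoverlap)
  h2 <- overlap_pairs(a$second, subjects, maxgap, minoverlap)
  hits <- unique(rbind(h1, h2))
  names(hits) <- c("query", "subject")
  sort_hits(hits)
}

#' Two-dimensional overlap with a pair of regions
#'
#' An interaction overlaps the pair `(region_a, region_b)` when one
#' anchor overlaps `region_a` and the other overlaps `region_b`, in
#' either assignment. Identifies interactions linking two specific loci,
#' e.g. a gene and its enhancer; the result is symmetric in the two
#' regions.
#'
#' @param x An [InteractionTable-class].
#' @param region_a,region_b Single regions (one-row data frames).
#' @inheritParams region_overlap
#' @return Logical vector, one value per interaction.
#' @export
overlaps_pair <- function(x, region_a, region_b, maxgap = 0, minoverlap = 1) {
  region_a <- validate_regions(region_a, what = "region_a")
  region_b <- validate_regions(region_b, what = "region_b")
  if (nrow(region_a) != 1L || nrow(region_b) != 1L) {
    stop("region_a and region_b must each be a single region", call. = FALSE)
  }
  a <- anchors(x)
  h1a <- region_overlap(a$first, region_a, maxgap, minoverlap)
  h1b <- region_overlap(a$first, region_b, maxgap, minoverlap)
  h2a <- region_overlap(a$second, region_a, maxgap, minoverlap)
  h2b <- region_overlap(a$second, region_b, maxgap, minoverlap)
  (h1a & h2b) | (h1b & h2a)
}

#' Two-dimensional overlaps between two interaction tables
#'
#' Interactions i (in `x`) and j (in `y`) overlap when their anchor
#' regions overlap pairwise. By default either pairing is accepted:
#' (x.anchor1 ~ y.anchor1 and x.anchor2 ~ y.anchor2) or the crossed
#' assignment. Set `match_slots = TRUE` to require the same-slot pairing
#' only. Use this to relate similar interactions across objects or
#' experiments.
#'
#' @param x,y [InteractionTable-class] objects (region sets may differ).
#' @inheritParams region_overlap
#' @param match_slots If `TRUE`, only slot-matched anchor pairings count.
#' @return data.frame with columns `query` (row of `x`) and `subject`
#'   (row of `y`), sorted, duplicate-free.
#' @export
overlaps_interactions <- function(x, y, maxgap = 0, minoverlap = 1,
                                  match_slots = FALSE) {
  check_overlap_args(maxgap, minoverlap)
  ax <- anchors(x)
  ay <- anchors(y)
  pair_flags <- function(pa, pb) {
    m <- matrix(FALSE, nrow = length(x), ncol = length(y))
    hits <- overlap_pairs(pa, pb, maxgap, minoverlap)
    m[cbind(hits$i, hits$j)] <- TRUE
    m
  }
  keep <- pair_flags(ax$first, ay$first) & pair_flags(ax$second, ay$second)
  if (!match_slots) {
    keep <- keep |
      (pair_flags(ax$first, ay$second) & pair_flags(ax$second, ay$first))
  }
  idx <- which(keep, arr.ind = TRUE)
  sort_hits(data.frame(query = as.integer(idx[, 1L]),
                       subject = as.integer(idx[, 2L])))
}

#' Link regions of interest through interactions
#'
#' Finds interactions whose two anchors land in two subject sets: triplet
#' `(interaction, subject1, subject2)` is reported when one anchor
#' overlaps `subjects1[subject1]` and the other overlaps
#' `subjects2[subject2]` (both anchor assignments are tried). With a
#' single set (`subjects2 = NULL`) the set is linked against itself:
#' triplets are canonicalized to `subject1 <= subject2` and deduplicated,
#' so e.g. gene-gene or gene-enhancer contacts fall out directly.
#' Self-pairs (both anchors hitting the same subject) are kept; filter
#' afterwards if unwanted.
#'
#' @param x An [InteractionTable-class].
#' @param subjects1 Region data frame (e.g. genes).
#' @param subjects2 Optional second region data frame (e.g. enhancers).
#' @inheritParams region_overlap
#' @return data.frame with integer columns `interaction`, `subject1`,
#'   `subject2`, sorted by all three.
#' @export
link_overlaps <- function(x, subjects1, subjects2 = NULL,
                          maxgap = 0, minoverlap = 1) {
  subjects1 <- validate_regions(subjects1, what = "subjects1 region")
  single_set <- is.null(subjects2)
  subjects2 <- if (single_set) subjects1 else
    validate_regions(subjects2, what = "subjects2 region")
  check_overlap_args(maxgap, minoverlap)
  a <- anchors(x)
  join <- function(anchor_a, anchor_b) {
    ha <- overlap_pairs(anchor_a, subjects1, maxgap, minoverlap)
    hb <- overlap_pairs(anchor_b, subjects2, maxgap, minoverlap)
    merged <- merge(ha, hb, by = "i")
    data.frame(interaction = merged$i,
               subject1 = merged$j.x, subject2 = merged$j.y)
  }
  out <- rbind(join(a$first, a$second), join(a$second, a$first))
  if (single_set && nrow(out)) {
    swap <- out$subject1 > out$subject2
    tmp <- out$subject1[swap]
    out$subject1[swap] <- out$subject2[swap]
    out$subject2[swap] <- tmp
  }
  out <- unique(out)
  sort_hits(out)
}
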