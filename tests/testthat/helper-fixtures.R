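# Seeded random fixtures; callers set.seed() before use.

rand_regions <- function(n, chroms = c("chr1", "chr2", "chr3"),
                         max_pos = 10000, max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  gregions(chrom, start, start + width)
}

rand_table <- function(n, chroms = c("chr1", "chr2", "chr3"),
                       max_pos = 10000, max_width = 500,
                       metadata = TRUE, strict = FALSE) {
  meta <- if (metadata) {
    data.frame(name = sprintf("loop%d", seq_len(n)),
               score = sample(c(seq_len(50), seq_len(20) + 0.5), n,
                              replace = TRUE),
               strand1 = sample(c("+", "-", "."), n, replace = TRUE),
               strand2 = sample(c("+", "-", "."), n, replace = TRUE))
  }
  make_interactions(rand_regions(n, chroms, max_pos, max_width),
                    rand_regions(n, chroms, max_pos, max_width),
                    metadata = meta, strict = strict)
}

# The worked three-interaction fixture used for linearization checks:
# bait chr1:0-1000, counts rows [5,2], [1,0], [7,7].
worked_linearize_fixture <- function() {
  tab <- make_interactions(
    gregions(c("chr1", "chr1", "chr2"), c(100, 300, 0), c(200, 400, 50)),
    gregions(c("chr2", "chr1", "chr2"), c(50, 5000, 500), c(100, 6000, 600))
  )
  make_assay_set(tab, list(counts = matrix(c(5, 1, 7, 2, 0, 7), nrow = 3)))
}
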