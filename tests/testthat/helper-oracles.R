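# Independent brute-force oracles: scalar predicates expanded by explicit
# loops over all combinations. Deliberately naive; never call the package's
# vectorized query paths.

bf_region_overlap <- function(a, b, maxgap = 0, minoverlap = 1) {
  if (a$chrom != b$chrom) return(FALSE)
  inter <- min(a$end, b$end) - max(a$start, b$start)
  if (inter >= minoverlap) return(TRUE)
  if (minoverlap == 1 && inter <= 0) {
    gap <- max(a$start, b$start) - min(a$end, b$end)
    if (gap <= maxgap) return(TRUE)
  }
  FALSE
}

row_of <- function(df, i) df[i, , drop = FALSE]

bf_overlaps_any <- function(tab, subjects, maxgap = 0, minoverlap = 1) {
  a <- anchors(tab)
  out <- NULL
  for (i in seq_len(length(tab))) {
    for (j in seq_len(nrow(subjects))) {
      if (bf_region_overlap(row_of(a$first, i), row_of(subjects, j),
                            maxgap, minoverlap) ||
          bf_region_overlap(row_of(a$second, i), row_of(subjects, j),
                            maxgap, minoverlap)) {
        out <- rbind(out, data.frame(query = i, subject = j))
      }
    }
  }
  if (is.null(out)) data.frame(query = integer(0), subject = integer(0))
  else out
}

bf_overlaps_pair <- function(tab, ra, rb, maxgap = 0, minoverlap = 1) {
  a <- anchors(tab)
  vapply(seq_len(length(tab)), function(i) {
    a1 <- row_of(a$first, i); a2 <- row_of(a$second, i)
    (bf_region_overlap(a1, ra, maxgap, minoverlap) &&
       bf_region_overlap(a2, rb, maxgap, minoverlap)) ||
      (bf_region_overlap(a1, rb, maxgap, minoverlap) &&
         bf_region_overlap(a2, ra, maxgap, minoverlap))
  }, logical(1))
}

bf_overlaps_interactions <- function(t1, t2, maxgap = 0, minoverlap = 1,
                                     match_slots = FALSE) {
  a <- anchors(t1); b <- anchors(t2)
  out <- NULL
  for (i in seq_len(length(t1))) {
    for (j in seq_len(length(t2))) {
      a1 <- row_of(a$first, i); a2 <- row_of(a$second, i)
      b1 <- row_of(b$first, j); b2 <- row_of(b$second, j)
      hit <- (bf_region_overlap(a1, b1, maxgap, minoverlap) &&
                bf_region_overlap(a2, b2, maxgap, minoverlap))
      if (!match_slots) {
        hit <- hit || (bf_region_overlap(a1, b2, maxgap, minoverlap) &&
                         bf_region_overlap(a2, b1, maxgap, minoverlap))
      }
      if (hit) out <- rbind(out, data.frame(query = i, subject = j))
    }
  }
  if (is.null(out)) data.frame(query = integer(0), subject = integer(0))
  else out
}

bf_link_overlaps <- function(tab, s1, s2 = NULL, maxgap = 0, minoverlap = 1) {
  single <- is.null(s2)
  if (single) s2 <- s1
  a <- anchors(tab)
  out <- NULL
  for (i in seq_len(length(tab))) {
    a1 <- row_of(a$first, i); a2 <- row_of(a$second, i)
    for (p in seq_len(nrow(s1))) {
      for (q in seq_len(nrow(s2))) {
        hit <- (bf_region_overlap(a1, row_of(s1, p), maxgap, minoverlap) &&
                  bf_region_overlap(a2, row_of(s2, q), maxgap, minoverlap)) ||
          (bf_region_overlap(a2, row_of(s1, p), maxgap, minoverlap) &&
             bf_region_overlap(a1, row_of(s2, q), maxgap, minoverlap))
        if (hit) {
          pp <- p; qq <- q
          if (single && pp > qq) { tmp <- pp; pp <- qq; qq <- tmp }
          out <- rbind(out, data.frame(interaction = i, subject1 = pp,
                                       subject2 = qq))
        }
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(interaction = integer(0), subject1 = integer(0),
                      subject2 = integer(0)))
  }
  out <- unique(out)
  out <- out[order(out$interaction, out$subject1, out$subject2), ]
  rownames(out) <- NULL
  out
}

# Rule for 4C-style extraction: keep interactions where exactly one anchor
# overlaps the bait, report the other anchor.
bf_linearize_rows <- function(tab, bait, keep_double = FALSE) {
  a <- anchors(tab)
  keep <- integer(0)
  reg <- NULL
  for (i in seq_len(length(tab))) {
    h1 <- bf_region_overlap(row_of(a$first, i), bait)
    h2 <- bf_region_overlap(row_of(a$second, i), bait)
    if (h1 + h2 == 1L) {
      keep <- c(keep, i)
      reg <- rbind(reg, if (h1) row_of(a$second, i) else row_of(a$first, i))
    } else if (h1 && h2 && keep_double) {
      keep <- c(keep, i)
      ids <- anchor_ids(tab)
      lo <- if (ids$anchor1[i] <= ids$anchor2[i]) row_of(a$first, i)
            else row_of(a$second, i)
      reg <- rbind(reg, lo)
    }
  }
  if (is.null(reg)) reg <- gregions(character(0), numeric(0), numeric(0))
  rownames(reg) <- NULL
  list(rows = keep, regions = reg)
}

sort_pairs <- function(df) {
  df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_hits <- function(got, want) {
  rownames(got) <- NULL
  rownames(want) <- NULL
  for (k in seq_along(got)) got[[k]] <- as.integer(got[[k]])
  for (k in seq_along(want)) want[[k]] <- as.integer(want[[k]])
  expect_identical(got, want)
}
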