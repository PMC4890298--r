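#' Flag intra-chromosomal (cis) interactions
#'
#' @param x An [InteractionTable-class].
#' @return Logical vector: `TRUE` when both anchors are on the same
#'   chromosome, `FALSE` for inter-chromosomal (trans) pairs.
#' @export
is_intra <- function(x) {
  a <- anchors(x)
  a$first$chrom == a$second$chrom
}

#' Linear-genome distance between anchor regions
#'
#' Computes, per interaction, the distance between the two anchors on the
#' linear genome — the quantity used when fitting or inspecting the
#' distance-dependent decay of contact frequency. With L the anchor with
#' the smaller (start, end) and R the other:
#'
#' * `mid`: absolute difference of interval midpoints `(start + end) / 2`;
#'   may be half-integral and is reported as-is.
#' * `gap`: `max(0, R.start - L.end)` — bases strictly between the
#'   anchors, 0 when they touch or overlap.
#' * `span`: `max(end) - min(start)` — total footprint of the pair.
#'
#' Inter-chromosomal pairs have no linear distance and yield `NA` in
#' every mode. For disjoint cis pairs, `span = gap + width1 + width2`.
#'
#' @param x An [InteractionTable-class].
#' @param mode One of `"mid"`, `"gap"`, `"span"`.
#' @return Numeric vector in base pairs, `NA` for trans pairs.
#' @examples
#' t <- make_interactions(gregions("chr1", 100, 200),
#'                        gregions("chr1", 300, 400))
#' pair_distance(t, "mid")   # 200
#' pair_distance(t, "gap")   # 100
#' pair_distance(t, "span")  # 300
#' @export
pair_distance <- function(x, mode = c("mid", "gap", "span")) {
  mode <- match.arg(mode)
  a <- anchors(x)
  cis <- a$first$chrom == a$second$chrom
  s1 <- a$first$start; e1 <- a$first$end
  s2 <- a$second$start; e2 <- a$second$end
  left_first <- s1 < s2 | (s1 == s2 & e1 <= e2)
  ls <- ifelse(left_first, s1, s2); le <- ifelse(left_first, e1, e2)
  rs <- ifelse(left_first, s2, s1); re <- ifelse(left_first, e2, e1)
  out <- switch(mode,
    mid = abs((rs + re) / 2 - (ls + le) / 2),
    gap = pmax(0, rs - le),
    span = pmax(e1, e2) - pmin(s1, s2)
  )
  out[!cis] <- NA_real_
  out
}

#' Minimum bounding boxes for groups of interactions
#'
#' Summarizes each group of interactions by the smallest axis-aligned
#' rectangle in the interaction space containing all of its members. Rows
#' are first canonicalized with [swap_anchors()] so slot membership is
#' well defined; box 1 then spans the slot-1 anchors (min start to max
#' end on their common chromosome) and box 2 the slot-2 anchors. Within a
#' group each slot must sit on a single chromosome.
#'
#' @param x An [InteractionTable-class].
#' @param grouping Vector of group labels, one per interaction. Groups
#'   are reported in order of first appearance.
#' @return data.frame with columns `group`, `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `n_members`.
#' @export
bounding_box <- function(x, grouping) {
  if (length(grouping) != length(x)) {
    stop("grouping must supply one label per interaction", call. = FALSE)
  }
  if (length(x) == 0L) {
    return(data.frame(group = character(0), chrom1 = character(0),
                      start1 = numeric(0), end1 = numeric(0),
                      chrom2 = character(0), start2 = numeric(0),
                      end2 = numeric(0), n_members = integer(0)))
  }
  x <- swap_anchors(x)
  a <- anchors(x)
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  rows <- lapply(groups, function(g) {
    sel <- grouping == g
    c1 <- unique(a$first$chrom[sel])
    c2 <- unique(a$second$chrom[sel])
    if (length(c1) > 1L || length(c2) > 1L) {
      stop(sprintf("group '%s' mixes chromosomes within one anchor slot", g),
           call. = FALSE)
    }
    data.frame(group = g,
               chrom1 = c1, start1 = min(a$first$start[sel]),
               end1 = max(a$first$end[sel]),
               chrom2 = c2, start2 = min(a$second$start[sel]),
               end2 = max(a$second$end[sel]),
               n_members = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
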