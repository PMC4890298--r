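#' Construct a table of genomic regions
#'
#' Regions are plain data frames with columns `chrom`, `start`, `end` and
#' `strand`, using 0-based half-open coordinates throughout (the BEDPE/BED
#' convention). A "region" elsewhere in this package always means a row of
#' such a frame; functions taking a single region accept a one-row frame.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector of 0-based inclusive start offsets (>= 0).
#' @param end Integer vector of exclusive end offsets; must satisfy
#'   `start < end` (zero-width regions are rejected).
#' @param strand Strand per region, one of `"+"`, `"-"`, `"."`; recycled.
#' @param name Optional character labels, kept as a `name` column.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `name` when supplied).
#' @examples
#' gregions(c("chr1", "chr2"), c(100, 0), c(200, 500))
#' @export
gregions <- function(chrom, start, end, strand = ".", name = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(name)) {
    df$name <- rep_len(as.character(name), n)
  }
  validate_regions(df)
  df
}

# Checks the region invariants; errors name the first offending row.
validate_regions <- function(df, what = "region") {
  if (!is.data.frame(df) ||
      !all(c("chrom", "start", "end") %in% names(df))) {
    stop("expected a region data frame with columns chrom/start/end",
         call. = FALSE)
  }
  if (is.null(df$strand)) {
    df$strand <- rep(".", nrow(df))
  }
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom))
  if (length(bad)) {
    stop(sprintf("%s %d: chromosome name must be a non-empty string",
                 what, bad[1]), call. = FALSE)
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0)
  if (length(bad)) {
    stop(sprintf("%s %d: start must be a non-negative integer",
                 what, bad[1]), call. = FALSE)
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s %d: start (%s) must be < end (%s); zero-width regions are not allowed",
                 what, bad[1], format_coord(df$start[bad[1]]),
                 format_coord(df$end[bad[1]])), call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("%s %d: strand must be one of '+', '-', '.'",
                 what, bad[1]), call. = FALSE)
  }
  invisible(df)
}

# Strips a region frame down to the four canonical columns.
region_core <- function(df) {
  out <- df[, c("chrom", "start", "end"), drop = FALSE]
  out$strand <- if (is.null(df$strand)) rep(".", nrow(df)) else df$strand
  rownames(out) <- NULL
  out
}

# Identity key: coordinate + strand. "\r" cannot occur in chromosome names
# read from tab-separated text, so the key is collision-free.
region_key <- function(df) {
  paste(df$chrom, df$start, df$end,
        if (is.null(df$strand)) "." else df$strand, sep = "\r")
}

strand_rank <- function(strand) match(strand, c("+", "-", "."))

# Canonical order: chromosome (per supplied level order), start, end,
# strand (+, -, .). Radix sort for a locale-independent ordering.
region_order <- function(df, chrom_levels) {
  order(match(df$chrom, chrom_levels), df$start, df$end,
        strand_rank(df$strand), method = "radix")
}

default_chrom_levels <- function(chroms) {
  sort(unique(as.character(chroms)), method = "radix")
}

#' Parse a region string
#'
#' Accepts `"chrom:start-end"` with 0-based half-open coordinates, e.g.
#' `"chr1:0-1000"`.
#'
#' @param x Character vector of region strings.
#' @return A region data frame (see [gregions()]).
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad)) {
    stop(sprintf("cannot parse region '%s'; expected chrom:start-end",
                 x[bad[1]]), call. = FALSE)
  }
  gregions(
    chrom = vapply(m, `[[`, "", 2L),
    start = as.numeric(vapply(m, `[[`, "", 3L)),
    end = as.numeric(vapply(m, `[[`, "", 4L))
  )
}

#' Format regions as strings
#'
#' Inverse of [parse_region()]: renders each region as
#' `"chrom:start-end"` (0-based half-open).
#'
#' @param df A region data frame.
#' @return Character vector.
#' @export
region_label <- function(df) {
  paste0(df$chrom, ":", format_coord(df$start), "-", format_coord(df$end))
}

# Integer-valued coordinates print without decimal point.
format_coord <- function(x) {
  sprintf("%.0f", x)
}

# General numeric formatter for text output: integers bare, half-integral
# values (e.g. midpoints) with one decimal, anything else via as.character.
format_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "."
  ok <- !is.na(x)
  whole <- ok & x == round(x)
  half <- ok & !whole & (2 * x) == round(2 * x)
  out[whole] <- sprintf("%.0f", x[whole])
  out[half] <- sprintf("%.1f", x[half])
  rest <- ok & !whole & !half
  out[rest] <- as.character(x[rest])
  out
}
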