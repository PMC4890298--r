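#' Read interactions from a BEDPE file
#'
#' Parses tab-separated BEDPE: chrom1, start1, end1, chrom2, start2,
#' end2, then optional name, score, strand1, strand2 and any further
#' columns. Coordinates are 0-based half-open and taken verbatim. Lines
#' starting with `#` or `track` are skipped. `.` in the name or score
#' column becomes `NA`; the score column is numeric when every non-`.`
#' entry parses as a number, otherwise kept as text. Columns beyond 10
#' are preserved as opaque `extra<k>` metadata and re-emitted by
#' [write_bedpe()]. Only the columns present in the file become metadata
#' columns, so a 6-column file round-trips to 6 columns.
#'
#' @param path Path to a BEDPE file (or a connection).
#' @param strict Passed to [make_interactions()].
#' @param chrom_levels Optional chromosome ordering for the region set.
#' @return An [InteractionTable-class] with metadata columns among
#'   `name`, `score`, `strand1`, `strand2`, `extra1`, ...
#' @export
read_bedpe <- function(path, strict = FALSE, chrom_levels = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^track($|[ \t])", lines) &
    nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- vapply(fields, length, 1L)
  if (any(ncols < 6L)) {
    stop(sprintf("line %d: BEDPE needs at least 6 tab-separated columns",
                 lineno[which(ncols < 6L)[1]]), call. = FALSE)
  }
  n <- length(fields)
  col <- function(k) vapply(fields, function(f) {
    if (length(f) >= k) f[[k]] else "."
  }, "")

  coord <- function(k, what) {
    raw <- col(k)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val != floor(val))
    if (length(bad)) {
      stop(sprintf("line %d: %s '%s' is not an integer",
                   lineno[bad[1]], what, raw[bad[1]]), call. = FALSE)
    }
    val
  }
  mk_anchor <- function(chrom, s, e, slot) {
    bad <- which(s < 0)
    if (length(bad)) {
      stop(sprintf("line %d: negative start in anchor %d",
                   lineno[bad[1]], slot), call. = FALSE)
    }
    bad <- which(s >= e)
    if (length(bad)) {
      stop(sprintf("line %d: start %s >= end %s in anchor %d",
                   lineno[bad[1]], format_coord(s[bad[1]]),
                   format_coord(e[bad[1]]), slot), call. = FALSE)
    }
    gregions(chrom, s, e)
  }
  a1 <- mk_anchor(col(1L), coord(2L, "start1"), coord(3L, "end1"), 1L)
  a2 <- mk_anchor(col(4L), coord(5L, "start2"), coord(6L, "end2"), 2L)

  maxc <- if (n) max(ncols) else 6L
  meta <- data.frame(matrix(nrow = n, ncol = 0L))
  dotna <- function(v) ifelse(v == ".", NA_character_, v)
  if (maxc >= 7L) meta$name <- dotna(col(7L))
  if (maxc >= 8L) {
    raw <- dotna(col(8L))
    num <- suppressWarnings(as.numeric(raw))
    meta$score <- if (all(is.na(num) == is.na(raw))) num else raw
  }
  if (maxc >= 9L) meta$strand1 <- check_strand(col(9L), lineno, 9L)
  if (maxc >= 10L) meta$strand2 <- check_strand(col(10L), lineno, 10L)
  if (maxc >= 11L) {
    for (k in 11L:maxc) meta[[sprintf("extra%d", k - 10L)]] <- col(k)
  }
  make_interactions(a1, a2, metadata = meta, strict = strict,
                    chrom_levels = chrom_levels)
}

# "" means standard output for the text writers below.
out_con <- function(path) if (identical(path, "")) stdout() else path

check_strand <- function(v, lineno, colno) {
  bad <- which(!v %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("line %d: column %d must be a strand (+, -, .), got '%s'",
                 lineno[bad[1]], colno, v[bad[1]]), call. = FALSE)
  }
  v
}

#' Write interactions to a BEDPE file
#'
#' Emits one tab-separated line per interaction in table order. The
#' optional columns name/score/strand1/strand2/extra* are written up to
#' the last one present in the metadata, with `.` filling missing values
#' and absent intermediate columns, so `read_bedpe(write_bedpe(x))`
#' reproduces `x` exactly and files written by this function round-trip
#' byte-identically.
#'
#' @param x An [InteractionTable-class].
#' @param path Output path (or connection); `""` writes to stdout.
#' @return Invisibly, the number of records written.
#' @export
write_bedpe <- function(x, path = "") {
  writeLines(format_bedpe(x), con = out_con(path))
  invisible(length(x))
}

format_bedpe <- function(x) {
  n <- length(x)
  a <- anchors(x)
  meta <- x@metadata
  extras <- grep("^extra[0-9]+$", names(meta), value = TRUE)
  extras <- extras[order(as.integer(sub("extra", "", extras)))]
  opt_names <- c("name", "score", "strand1", "strand2")
  opt_upto <- if (length(extras)) 4L
  else max(0L, which(opt_names %in% names(meta)))
  cols <- list(a$first$chrom, format_coord(a$first$start),
               format_coord(a$first$end),
               a$second$chrom, format_coord(a$second$start),
               format_coord(a$second$end))
  dot <- rep(".", n)
  for (k in seq_len(opt_upto)) {
    v <- meta[[opt_names[k]]]
    cols[[length(cols) + 1L]] <- if (is.null(v)) dot
    else if (is.numeric(v)) format_num(v)
    else ifelse(is.na(v), ".", as.character(v))
  }
  for (e in extras) cols[[length(cols) + 1L]] <- as.character(meta[[e]])
  if (n == 0L) return(character(0))
  do.call(paste, c(cols, list(sep = "\t")))
}

#' Read regions from a BED file
#'
#' Accepts BED3/BED4 (chrom, start, end, optional name); further columns
#' are ignored. Header, `#` and `track` lines are skipped; coordinates
#' are 0-based half-open.
#'
#' @param path Path to a BED file (or a connection).
#' @return A region data frame, with a `name` column when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^(track|browser)($|[ \t])", lines) &
    nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- vapply(fields, length, 1L)
  if (any(ncols < 3L)) {
    stop(sprintf("line %d: BED needs at least 3 tab-separated columns",
                 lineno[which(ncols < 3L)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e) |
                 s < 0 | s >= e)
  if (length(bad)) {
    stop(sprintf("line %d: malformed BED coordinates", lineno[bad[1]]),
         call. = FALSE)
  }
  name <- if (length(fields) && max(ncols) >= 4L) {
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", "")
  } else NULL
  if (length(fields) == 0L) {
    return(gregions(character(0), numeric(0), numeric(0)))
  }
  gregions(chrom, s, e, name = name)
}

#' Write regions to a BED file
#'
#' @param x A region data frame.
#' @param path Output path; `""` writes to stdout.
#' @return Invisibly, the number of records.
#' @export
write_bed <- function(x, path = "") {
  x <- validate_regions(x)
  lines <- paste(x$chrom, format_coord(x$start), format_coord(x$end),
                 sep = "\t")
  if (!is.null(x$name)) lines <- paste(lines, x$name, sep = "\t")
  writeLines(lines, con = out_con(path))
  invisible(nrow(x))
}

#' Export a linear track as bedGraph
#'
#' Writes one bedGraph file per assay per sample, named
#' `<prefix>.<assay>.<sample>.bedGraph`, each line
#' `chrom<TAB>start<TAB>end<TAB>value` in track order. Sample labels come
#' from the `sample` column of the sample metadata when present, else
#' `S1..Sm`.
#'
#' @param x A [LinearTrack-class].
#' @param prefix Output path prefix (may include directories).
#' @return Invisibly, the paths written.
#' @export
write_bedgraph <- function(x, prefix) {
  m <- nrow(x@sample_metadata)
  samples <- if (!is.null(x@sample_metadata$sample)) {
    as.character(x@sample_metadata$sample)
  } else sprintf("S%d", seq_len(m))
  paths <- character(0)
  for (aname in names(x@assays)) {
    mat <- x@assays[[aname]]
    for (k in seq_len(ncol(mat))) {
      p <- sprintf("%s.%s.%s.bedGraph", prefix, aname, samples[k])
      writeLines(paste(x@regions$chrom, format_coord(x@regions$start),
                       format_coord(x@regions$end), format_num(mat[, k]),
                       sep = "\t"), con = p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Contact-matrix text serialization
#'
#' `write_contact_coo` writes one `row_region<TAB>col_region<TAB>value`
#' triplet per non-empty cell (with a header line); `read_contact_coo`
#' rebuilds a sparse [ContactMatrix-class] from such a file, with rows
#' and columns in order of first appearance. `write_contact_tsv` writes
#' the dense grid with region labels as row/column headers and `.` for
#' empty cells; `read_contact_tsv` is its inverse (dense backend).
#'
#' @param x A [ContactMatrix-class].
#' @param path File path; `""` writes to stdout.
#' @return Writers return the path invisibly; readers a
#'   [ContactMatrix-class].
#' @export
write_contact_coo <- function(x, path = "") {
  if (x@backend == "dense") {
    filled <- which(!is.na(x@values), arr.ind = TRUE)
    i <- filled[, 1L]; j <- filled[, 2L]; v <- x@values[filled]
  } else {
    trip <- Matrix::summary(x@values)
    i <- trip$i; j <- trip$j; v <- trip$x
  }
  ord <- order(i, j, method = "radix")
  rl <- region_label(cm_regions(x, "row"))
  cl <- region_label(cm_regions(x, "col"))
  writeLines(c("row_region\tcol_region\tvalue",
               paste(rl[i[ord]], cl[j[ord]], format_num(v[ord]), sep = "\t")),
             con = out_con(path))
  invisible(path)
}

#' @rdname write_contact_coo
#' @export
read_contact_coo <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^row_region\t", lines[1])) {
    lines <- lines[-1L]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 3L)
  if (length(bad)) {
    stop(sprintf("COO line %d: expected 3 tab-separated columns", bad[1]),
         call. = FALSE)
  }
  rlab <- vapply(fields, `[[`, "", 1L)
  clab <- vapply(fields, `[[`, "", 2L)
  v <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(v)) stop("COO value column must be numeric", call. = FALSE)
  rows <- parse_region(unique(rlab))
  cols <- parse_region(unique(clab))
  built <- build_region_set(rbind(rows, cols))
  ri <- built$index_map[seq_len(nrow(rows))]
  ci <- built$index_map[nrow(rows) + seq_len(nrow(cols))]
  grid <- Matrix::sparseMatrix(i = match(rlab, unique(rlab)),
                               j = match(clab, unique(clab)),
                               x = v, dims = c(nrow(rows), nrow(cols)))
  new("ContactMatrix", region_set = built$region_set,
      row_indices = as.integer(ri), col_indices = as.integer(ci),
      values = grid, backend = "sparse")
}

#' @rdname write_contact_coo
#' @export
write_contact_tsv <- function(x, path = "") {
  vals <- cm_values(x)
  header <- paste(c("region", colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], format_num(vals[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), con = out_con(path))
  invisible(path)
}

#' @rdname write_contact_coo
#' @export
read_contact_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty dense matrix file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  clab <- fields[[1L]][-1L]
  rlab <- vapply(fields[-1L], `[[`, "", 1L)
  grid <- matrix(NA_real_, nrow = length(rlab), ncol = length(clab))
  for (i in seq_along(rlab)) {
    row <- fields[[i + 1L]][-1L]
    if (length(row) != length(clab)) {
      stop(sprintf("dense matrix line %d: expected %d value columns",
                   i + 1L, length(clab)), call. = FALSE)
    }
    grid[i, ] <- suppressWarnings(as.numeric(ifelse(row == ".", NA, row)))
  }
  rows <- parse_region(rlab)
  cols <- parse_region(clab)
  built <- build_region_set(rbind(rows, cols))
  new("ContactMatrix", region_set = built$region_set,
      row_indices = as.integer(built$index_map[seq_len(nrow(rows))]),
      col_indices = as.integer(built$index_map[nrow(rows) +
                                                 seq_len(nrow(cols))]),
      values = grid, backend = "dense")
}
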