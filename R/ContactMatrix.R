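#' ContactMatrix: matrix view of the interaction space
#'
#' Represents interactions on the two-dimensional interaction space,
#' where cell (i, j) holds the measurement for an interaction between the
#' i-th row region and the j-th column region. Coordinates are not stored
#' per cell: rows and columns carry indices into a shared
#' [RegionSet-class].
#'
#' Two backends are supported. The dense backend is a base matrix with
#' `NA` as the explicit "empty cell" marker (distinct from a stored 0).
#' The sparse backend is a \pkg{Matrix} sparse matrix in which empty
#' cells are simply absent; to keep the two backends equivalent, stored
#' zeros are rejected in the sparse backend at validation.
#'
#' @slot region_set The shared [RegionSet-class].
#' @slot row_indices,col_indices Integer indices into the region set.
#' @slot values r x c matrix (dense) or `Matrix::dgCMatrix` (sparse).
#' @slot backend `"dense"` or `"sparse"`.
#' @seealso [inflate()], [deflate()]
#' @export
setClass("ContactMatrix", representation(
  region_set = "RegionSet",
  row_indices = "integer",
  col_indices = "integer",
  values = "ANY",
  backend = "character"
))

setValidity("ContactMatrix", function(object) {
  nr <- length(object@region_set)
  idx <- c(object@row_indices, object@col_indices)
  if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > nr))) {
    return(sprintf("row/col indices must lie in [1, %d]", nr))
  }
  d <- dim(object@values)
  if (d[1L] != length(object@row_indices) ||
      d[2L] != length(object@col_indices)) {
    return("value grid dimensions must match the row/col index lengths")
  }
  if (!object@backend %in% c("dense", "sparse")) {
    return("backend must be 'dense' or 'sparse'")
  }
  if (object@backend == "sparse") {
    if (!methods::is(object@values, "sparseMatrix")) {
      return("sparse backend requires a Matrix sparse matrix")
    }
    trip <- Matrix::summary(object@values)
    if (any(trip$x == 0)) {
      return("sparse backend cannot store zero values (0 would be indistinguishable from an empty cell); use the dense backend")
    }
  } else if (!is.matrix(object@values)) {
    return("dense backend requires a base matrix")
  }
  TRUE
})

#' @describeIn ContactMatrix-class grid dimensions (rows, columns).
#' @param x A ContactMatrix.
#' @export
setMethod("dim", "ContactMatrix", function(x) dim(x@values))

#' @rdname regions
#' @export
setMethod("regions", "ContactMatrix", function(x) x@region_set@regions)

#' Row and column regions of a contact matrix
#'
#' @param x A [ContactMatrix-class].
#' @param which `"row"` or `"col"`.
#' @return Region data frame in grid order.
#' @export
cm_regions <- function(x, which = c("row", "col")) {
  which <- match.arg(which)
  idx <- if (which == "row") x@row_indices else x@col_indices
  out <- x@region_set@regions[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dense view of the cell values
#'
#' @param x A [ContactMatrix-class].
#' @return A base matrix with `NA` marking empty cells, whatever the
#'   backend; row/column names are region labels.
#' @export
cm_values <- function(x) {
  if (x@backend == "dense") {
    m <- x@values
  } else {
    m <- matrix(NA_real_, nrow = nrow(x@values), ncol = ncol(x@values))
    trip <- Matrix::summary(x@values)
    m[cbind(trip$i, trip$j)] <- trip$x
  }
  dimnames(m) <- list(region_label(cm_regions(x, "row")),
                      region_label(cm_regions(x, "col")))
  m
}

#' @describeIn ContactMatrix-class transpose: swaps the row and column
#'   index sequences and transposes the value grid; backend preserved.
#' @export
setMethod("t", "ContactMatrix", function(x) {
  initialize(x, row_indices = x@col_indices, col_indices = x@row_indices,
             values = Matrix::t(x@values))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %d x %d (%s backend), %d filled cell(s)\n",
              nrow(object@values), ncol(object@values), object@backend,
              if (object@backend == "dense") sum(!is.na(object@values))
              else Matrix::nnzero(object@values)))
})

#' Inflate interactions into a contact matrix
#'
#' Fills a matrix whose rows and columns are caller-supplied region lists
#' (for example genome-wide bins from [tile_genome()]). Cell (i, j)
#' receives the value of any interaction whose two anchors are exactly
#' identical (coordinate + strand) to `row_regions[i]` and
#' `col_regions[j]`, in either anchor order; unfilled cells hold the
#' empty marker. Matching is by identity, not overlap — binning anchors
#' onto the grid is the caller's responsibility, which keeps
#' inflate/deflate a lossless pair.
#'
#' @param x An [InteractionTable-class].
#' @param row_regions,col_regions Region data frames defining the grid.
#' @param values Numeric vector, one value per interaction; defaults to
#'   the `value` metadata column, else 1 for every interaction.
#' @param combine How to resolve several interactions landing in one
#'   cell: `"error"` (default), `"sum"`, or `"first"` (input order).
#' @param backend `"dense"` or `"sparse"`.
#' @return A [ContactMatrix-class].
#' @export
inflate <- function(x, row_regions, col_regions, values = NULL,
                    combine = c("error", "sum", "first"),
                    backend = c("dense", "sparse")) {
  combine <- match.arg(combine)
  backend <- match.arg(backend)
  row_regions <- region_core(validate_regions(row_regions, "row region"))
  col_regions <- region_core(validate_regions(col_regions, "col region"))
  n <- length(x)
  if (is.null(values)) {
    values <- if ("value" %in% names(x@metadata)) x@metadata$value
              else rep(1, n)
  }
  if (length(values) != n) {
    stop("values must supply one number per interaction", call. = FALSE)
  }
  built <- build_region_set(rbind(row_regions, col_regions),
                            chrom_levels = x@region_set@chrom_levels)
  row_idx <- built$index_map[seq_len(nrow(row_regions))]
  col_idx <- built$index_map[nrow(row_regions) + seq_len(nrow(col_regions))]

  a <- anchors(x)
  k1 <- region_key(a$first)
  k2 <- region_key(a$second)
  row_pos <- split(seq_along(row_idx), region_key(row_regions))
  col_pos <- split(seq_along(col_idx), region_key(col_regions))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- rbind(
      expand_cells(row_pos[[k1[i]]], col_pos[[k2[i]]]),
      expand_cells(row_pos[[k2[i]]], col_pos[[k1[i]]])
    )
    if (nrow(hit)) {
      hit <- unique(hit)   # self-interactions reach the same cell twice
      cells[[i]] <- cbind(interaction = i, hit)
    }
  }
  trip <- do.call(rbind, cells)
  if (is.null(trip)) {
    trip <- data.frame(interaction = integer(0), r = integer(0),
                       c = integer(0))
  }
  trip$v <- values[trip$interaction]

  cell_id <- paste(trip$r, trip$c)
  if (combine == "error") {
    clash <- cell_id[duplicated(cell_id)]
    if (length(clash)) {
      at <- trip[match(clash[1], cell_id), ]
      stop(sprintf(
        "multiple interactions map to cell (%s, %s); use combine = 'sum' or 'first'",
        region_label(row_regions[at$r, , drop = FALSE]),
        region_label(col_regions[at$c, , drop = FALSE])), call. = FALSE)
    }
  } else if (combine == "sum") {
    v <- tapply(trip$v, cell_id, sum)
    first <- trip[!duplicated(cell_id), , drop = FALSE]
    first$v <- as.numeric(v[paste(first$r, first$c)])
    trip <- first
  } else {
    trip <- trip[!duplicated(cell_id), , drop = FALSE]
  }

  if (backend == "dense") {
    grid <- matrix(NA_real_, nrow = length(row_idx), ncol = length(col_idx))
    grid[cbind(trip$r, trip$c)] <- trip$v
  } else {
    if (any(trip$v == 0)) {
      stop("sparse backend cannot store zero values (0 would be indistinguishable from an empty cell); use the dense backend",
           call. = FALSE)
    }
    grid <- Matrix::sparseMatrix(i = trip$r, j = trip$c, x = trip$v,
                                 dims = c(length(row_idx), length(col_idx)))
  }
  new("ContactMatrix", region_set = built$region_set,
      row_indices = as.integer(row_idx), col_indices = as.integer(col_idx),
      values = grid, backend = backend)
}

expand_cells <- function(rpos, cpos) {
  if (is.null(rpos) || is.null(cpos)) {
    return(data.frame(r = integer(0), c = integer(0)))
  }
  data.frame(r = rep(rpos, times = length(cpos)),
             c = rep(cpos, each = length(rpos)))
}

#' Deflate a contact matrix into an interaction table
#'
#' The inverse view of [inflate()]: every non-empty cell (i, j) becomes
#' one interaction between the i-th row region and the j-th column
#' region, with the cell value attached as a `value` metadata column.
#' The output is canonically sorted. A stored 0 in the dense backend is a
#' real measurement and is retained. Because identity-matched inflation
#' fills the two symmetric cells of a square grid, a typical round trip
#' is `deflate()` followed by [swap_anchors()], [interaction_duplicated()]
#' filtering and [canonical_sort()].
#'
#' @param x A [ContactMatrix-class].
#' @return An [InteractionTable-class] with a `value` metadata column.
#' @export
deflate <- function(x) {
  if (x@backend == "dense") {
    filled <- which(!is.na(x@values), arr.ind = TRUE)
    i <- as.integer(filled[, 1L]); j <- as.integer(filled[, 2L])
    v <- x@values[filled]
  } else {
    trip <- Matrix::summary(x@values)
    i <- as.integer(trip$i); j <- as.integer(trip$j)
    v <- as.numeric(trip$x)
  }
  ref <- x@region_set@regions
  tab <- make_interactions(
    ref[x@row_indices[i], , drop = FALSE],
    ref[x@col_indices[j], , drop = FALSE],
    metadata = data.frame(value = v),
    chrom_levels = x@region_set@chrom_levels
  )
  canonical_sort(tab)$table
}
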