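#' AssaySet: interactions bound to experimental data
#'
#' Couples an [InteractionTable-class] (n interactions) with any number of
#' n x m data matrices — read-pair counts, normalized intensities, and so
#' on — where each column is an experimental sample. Sample-level
#' metadata (condition, library size, ...) is a data frame with one row
#' per sample.
#'
#' @slot interactions The [InteractionTable-class] (row domain).
#' @slot assays Named list of n x m matrices, identical dimensions.
#' @slot sample_metadata data.frame with m rows.
#' @slot global_metadata Named list of object-level metadata.
#' @seealso [make_assay_set()], [subset_assay_set()], [linearize()]
#' @export
setClass("AssaySet", representation(
  interactions = "InteractionTable",
  assays = "list",
  sample_metadata = "data.frame",
  global_metadata = "list"
))

setValidity("AssaySet", function(object) {
  n <- length(object@interactions)
  m <- nrow(object@sample_metadata)
  if (length(object@assays)) {
    nm <- names(object@assays)
    if (is.null(nm) || any(!nzchar(nm))) return("assays must be named")
    if (anyDuplicated(nm)) return("assay names must be unique")
    for (k in seq_along(object@assays)) {
      d <- dim(object@assays[[k]])
      if (is.null(d) || d[1L] != n || d[2L] != m) {
        return(sprintf("assay '%s' must be a %d x %d matrix", nm[k], n, m))
      }
    }
  }
  TRUE
})

#' Build an AssaySet
#'
#' @param interactions An [InteractionTable-class] with n rows.
#' @param assays Named list of n x m matrices (may be empty).
#' @param sample_metadata Optional data.frame with one row per sample;
#'   when absent, the sample count m is inferred from the first assay
#'   (0 if there are no assays).
#' @param global_metadata Named list of object-level metadata.
#' @return An [AssaySet-class].
#' @examples
#' t <- make_interactions(gregions("chr1", c(100, 300), c(200, 400)),
#'                        gregions("chr1", c(500, 700), c(600, 800)))
#' aset <- make_assay_set(t, list(counts = matrix(1:6, nrow = 2)))
#' @export
make_assay_set <- function(interactions, assays = list(),
                           sample_metadata = NULL, global_metadata = list()) {
  assays <- as.list(assays)
  if (length(assays)) {
    nm <- names(assays)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("every assay must be named", call. = FALSE)
    }
    if (anyDuplicated(nm)) {
      stop(sprintf("duplicate assay name '%s'", nm[duplicated(nm)][1]),
           call. = FALSE)
    }
    assays <- lapply(assays, as.matrix)
    m <- ncol(assays[[1L]])
  } else {
    m <- if (is.null(sample_metadata)) 0L else nrow(sample_metadata)
  }
  if (is.null(sample_metadata)) {
    sample_metadata <- data.frame(matrix(nrow = m, ncol = 0L))
  }
  n <- length(interactions)
  for (k in seq_along(assays)) {
    d <- dim(assays[[k]])
    if (d[1L] != n || d[2L] != nrow(sample_metadata)) {
      stop(sprintf(
        "assay '%s' is %d x %d but %d x %d is required",
        names(assays)[k], d[1L], d[2L], n, nrow(sample_metadata)),
        call. = FALSE)
    }
  }
  new("AssaySet", interactions = interactions, assays = assays,
      sample_metadata = sample_metadata, global_metadata = global_metadata)
}

#' Assay accessors
#'
#' @param x An AssaySet or LinearTrack.
#' @param name Assay name; defaults to the first assay.
#' @return `assay_names`: character vector; `get_assay`: the matrix;
#'   `sample_metadata`: the per-sample data.frame; `interactions`: the
#'   underlying [InteractionTable-class].
#' @export
assay_names <- function(x) names(x@assays)

#' @rdname assay_names
#' @export
get_assay <- function(x, name = NULL) {
  if (!length(x@assays)) stop("object has no assays", call. = FALSE)
  if (is.null(name)) return(x@assays[[1L]])
  if (!name %in% names(x@assays)) {
    stop(sprintf("no assay named '%s'", name), call. = FALSE)
  }
  x@assays[[name]]
}

#' @rdname assay_names
#' @export
sample_metadata <- function(x) x@sample_metadata

#' @rdname assay_names
#' @export
interactions <- function(x) x@interactions

#' @describeIn AssaySet-class dimensions: interactions x samples.
#' @param x An AssaySet.
#' @export
setMethod("dim", "AssaySet", function(x) {
  c(length(x@interactions), nrow(x@sample_metadata))
})

#' Subset an AssaySet by interactions and samples
#'
#' Rows select interactions (and the matching assay rows), columns select
#' samples (assay columns and sample metadata). Indices may repeat and
#' their order is respected; values are carried over unchanged.
#'
#' @param x An [AssaySet-class].
#' @param rows,cols Integer or logical indices; default keeps everything.
#' @return The subset [AssaySet-class].
#' @export
subset_assay_set <- function(x, rows = seq_len(dim(x)[1L]),
                             cols = seq_len(dim(x)[2L])) {
  d <- dim(x)
  rows <- seq_len(d[1L])[rows]
  cols <- seq_len(d[2L])[cols]
  if (anyNA(rows) || anyNA(cols)) {
    stop("subscript out of bounds", call. = FALSE)
  }
  smd <- x@sample_metadata[cols, , drop = FALSE]
  rownames(smd) <- NULL
  initialize(x,
             interactions = x@interactions[rows],
             assays = lapply(x@assays, function(a) a[rows, cols, drop = FALSE]),
             sample_metadata = smd)
}

#' @describeIn AssaySet-class `x[i, j]` sugar for [subset_assay_set()].
#' @param i,j Row (interaction) and column (sample) indices.
#' @param ...,drop Ignored.
#' @export
setMethod("[", "AssaySet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(dim(x)[1L])
  if (missing(j)) j <- seq_len(dim(x)[2L])
  subset_assay_set(x, i, j)
})

setMethod("show", "AssaySet", function(object) {
  d <- dim(object)
  cat(sprintf("AssaySet: %d interaction(s) x %d sample(s); assays: %s\n",
              d[1L], d[2L],
              if (length(object@assays)) {
                paste(names(object@assays), collapse = ", ")
              } else "<none>"))
})

#' LinearTrack: a 4C-like per-region signal track
#'
#' Result of [linearize()]: one genomic region per surviving interaction
#' (the anchor away from the bait) with the interaction's assay rows
#' carried over unchanged. Rows are not merged when several interactions
#' project onto the same region.
#'
#' @slot regions Region data frame, one row per track entry.
#' @slot bait The bait region used for extraction (one row).
#' @slot assays Named list of matrices, rows parallel to `regions`.
#' @slot sample_metadata As in [AssaySet-class].
#' @slot source_rows Integer indices of the originating interactions.
#' @export
setClass("LinearTrack", representation(
  regions = "data.frame",
  bait = "data.frame",
  assays = "list",
  sample_metadata = "data.frame",
  source_rows = "integer"
))

setValidity("LinearTrack", function(object) {
  n <- nrow(object@regions)
  for (k in seq_along(object@assays)) {
    if (nrow(object@assays[[k]]) != n) {
      return("assay row counts must equal the number of track regions")
    }
  }
  if (length(object@source_rows) != n) {
    return("source_rows must parallel the track regions")
  }
  TRUE
})

#' @rdname regions
#' @export
setMethod("regions", "LinearTrack", function(x) x@regions)

#' @describeIn LinearTrack-class number of track rows.
#' @param x A LinearTrack.
#' @export
setMethod("length", "LinearTrack", function(x) nrow(x@regions))

setMethod("show", "LinearTrack", function(object) {
  cat(sprintf("LinearTrack: %d region(s) around bait %s\n",
              nrow(object@regions), region_label(object@bait)))
})

#' Linearize interactions around a bait region
#'
#' Converts interaction data into a 4C-like format. Every interaction
#' with a one-dimensional overlap to the bait is identified; for each,
#' the anchor that does not overlap the bait is extracted together with
#' that interaction's assay values, yielding a signal track on the linear
#' genome that reads as "interaction strength between the bait and every
#' other locus". Interactions whose two anchors both overlap the bait
#' have no unambiguous non-bait anchor and are dropped by default;
#' `keep_double = TRUE` keeps them, reporting the canonical slot-1
#' (lower-sorted) anchor. Bait overlap uses the default
#' [region_overlap()] parameters (`maxgap = 0`, `minoverlap = 1`). Row
#' order follows the input order; rows are never aggregated.
#'
#' @param x An [AssaySet-class].
#' @param bait A single region of interest (one-row data frame), e.g. a
#'   gene promoter or enhancer.
#' @param keep_double Keep interactions with both anchors on the bait?
#' @return A [LinearTrack-class].
#' @export
linearize <- function(x, bait, keep_double = FALSE) {
  bait <- validate_regions(bait, what = "bait")
  if (nrow(bait) != 1L) stop("bait must be a single region", call. = FALSE)
  tab <- x@interactions
  a <- anchors(tab)
  h1 <- region_overlap(a$first, bait)
  h2 <- region_overlap(a$second, bait)
  single <- xor(h1, h2)
  both <- h1 & h2
  keep <- single | (keep_double & both)
  idx <- which(keep)
  # non-bait anchor; for double hits, the canonical lower-sorted anchor
  lower_first <- tab@anchor1 <= tab@anchor2
  take_first <- (single & h2) | (both & lower_first)
  src <- ifelse(take_first[idx], 1L, 2L)
  reg <- a$first[idx, , drop = FALSE]
  reg[src == 2L, ] <- a$second[idx[src == 2L], , drop = FALSE]
  rownames(reg) <- NULL
  new("LinearTrack",
      regions = reg, bait = region_core(bait),
      assays = lapply(x@assays, function(m) m[idx, , drop = FALSE]),
      sample_metadata = x@sample_metadata,
      source_rows = idx)
}
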