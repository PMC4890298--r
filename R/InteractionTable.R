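#' InteractionTable: anchor-indexed pairwise interactions
#'
#' Represents pairwise genomic interactions as parallel vectors of anchor
#' indices pointing into a shared [RegionSet-class]. A pair of indices
#' `(anchor1[i], anchor2[i])` is one interaction between the corresponding
#' reference regions; per-interaction metadata columns (names, scores,
#' strands, counts, p-values, ...) ride alongside, and free-form global
#' metadata describes the whole object.
#'
#' In strict mode every stored pair satisfies `anchor1 <= anchor2`
#' (indices into the canonically sorted region set), giving each
#' undirected interaction a unique representation.
#'
#' @slot region_set The shared [RegionSet-class].
#' @slot anchor1,anchor2 Integer anchor indices (1-based), equal length.
#' @slot metadata data.frame of per-interaction columns (n rows).
#' @slot global_metadata Named list of object-level metadata.
#' @slot strict Logical; enforce `anchor1 <= anchor2`.
#' @seealso [make_interactions()], [anchors()], [swap_anchors()]
#' @export
setClass("InteractionTable", representation(
  region_set = "RegionSet",
  anchor1 = "integer",
  anchor2 = "integer",
  metadata = "data.frame",
  global_metadata = "list",
  strict = "logical"
))

setValidity("InteractionTable", function(object) {
  n <- length(object@anchor1)
  if (length(object@anchor2) != n) {
    return("anchor1 and anchor2 must have equal length")
  }
  nr <- length(object@region_set)
  idx <- c(object@anchor1, object@anchor2)
  if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > nr))) {
    return(sprintf("anchor indices must lie in [1, %d]", nr))
  }
  if (nrow(object@metadata) != n && ncol(object@metadata) > 0L) {
    return("metadata columns must match the number of interactions")
  }
  if (isTRUE(object@strict) && any(object@anchor1 > object@anchor2)) {
    return("strict mode requires anchor1 <= anchor2 for every interaction")
  }
  TRUE
})

#' Construct an interaction table from paired anchor regions
#'
#' Builds the deduplicated reference region set from the union of both
#' anchor lists and stores each interaction as a pair of indices into it.
#'
#' @param anchors1,anchors2 Region data frames of equal length (row i of
#'   each is one interaction).
#' @param metadata Optional data.frame (or named list of columns) of
#'   per-interaction metadata, one row per interaction.
#' @param strict If `TRUE`, each pair is stored with `anchor1 <= anchor2`,
#'   swapping where necessary.
#' @param chrom_levels Optional explicit chromosome ordering (see
#'   [build_region_set()]).
#' @param global_metadata Named list of object-level metadata.
#' @return An [InteractionTable-class].
#' @examples
#' t <- make_interactions(gregions("chr1", 100, 200),
#'                        gregions("chr1", 500, 600))
#' anchors(t, "first")
#' @export
make_interactions <- function(anchors1, anchors2, metadata = NULL,
                              strict = FALSE, chrom_levels = NULL,
                              global_metadata = list()) {
  a1 <- region_core(validate_regions(anchors1, what = "anchor1 region"))
  a2 <- region_core(validate_regions(anchors2, what = "anchor2 region"))
  n <- nrow(a1)
  if (nrow(a2) != n) {
    stop(sprintf("anchor lists differ in length (%d vs %d)", n, nrow(a2)),
         call. = FALSE)
  }
  metadata <- as_metadata(metadata, n)
  built <- build_region_set(rbind(a1, a2), chrom_levels = chrom_levels)
  i1 <- built$index_map[seq_len(n)]
  i2 <- built$index_map[n + seq_len(n)]
  if (strict) {
    swap <- i1 > i2
    tmp <- i1[swap]
    i1[swap] <- i2[swap]
    i2[swap] <- tmp
  }
  new("InteractionTable",
      region_set = built$region_set,
      anchor1 = as.integer(i1), anchor2 = as.integer(i2),
      metadata = metadata, global_metadata = global_metadata,
      strict = strict)
}

as_metadata <- function(metadata, n) {
  if (is.null(metadata)) {
    return(data.frame(matrix(nrow = n, ncol = 0L)))
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(metadata) != n) {
    stop(sprintf("metadata has %d rows but there are %d interactions",
                 nrow(metadata), n), call. = FALSE)
  }
  rownames(metadata) <- NULL
  metadata
}

# Internal constructor from pre-resolved indices.
new_interaction_table <- function(region_set, anchor1, anchor2,
                                  metadata = NULL, global_metadata = list(),
                                  strict = FALSE) {
  new("InteractionTable", region_set = region_set,
      anchor1 = as.integer(anchor1), anchor2 = as.integer(anchor2),
      metadata = as_metadata(metadata, length(anchor1)),
      global_metadata = global_metadata, strict = strict)
}

#' @describeIn InteractionTable-class number of interactions.
#' @param x An InteractionTable.
#' @export
setMethod("length", "InteractionTable", function(x) length(x@anchor1))

#' @rdname regions
#' @export
setMethod("regions", "InteractionTable", function(x) x@region_set@regions)

#' Resolve anchor indices to regions
#'
#' @param x An [InteractionTable-class].
#' @param which `"first"`, `"second"` or `"both"`.
#' @return For `"first"`/`"second"`, a region data frame with one row per
#'   interaction; for `"both"`, a list with elements `first` and `second`.
#' @export
anchors <- function(x, which = c("both", "first", "second")) {
  which <- match.arg(which)
  ref <- x@region_set@regions
  pick <- function(idx) {
    out <- ref[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  switch(which,
         first = pick(x@anchor1),
         second = pick(x@anchor2),
         both = list(first = pick(x@anchor1), second = pick(x@anchor2)))
}

#' Anchor index accessor
#'
#' @param x An [InteractionTable-class].
#' @return A list with integer vectors `anchor1` and `anchor2` (1-based
#'   indices into `regions(x)`).
#' @export
anchor_ids <- function(x) {
  list(anchor1 = x@anchor1, anchor2 = x@anchor2)
}

#' Metadata accessors
#'
#' @param x An InteractionTable or AssaySet.
#' @return `interaction_metadata`: the per-interaction metadata
#'   data.frame; `global_metadata`: the named list of object metadata.
#' @export
interaction_metadata <- function(x) {
  if (is(x, "AssaySet")) x <- x@interactions
  x@metadata
}

#' @rdname interaction_metadata
#' @export
global_metadata <- function(x) x@global_metadata

#' Canonicalize anchor order within each interaction
#'
#' Swaps anchors row-wise so that `anchor1 <= anchor2` under the region
#' set's canonical order. Metadata and the region set are untouched; all
#' overlap and distance results are invariant under this operation.
#'
#' @param x An [InteractionTable-class].
#' @return The canonicalized table.
#' @export
swap_anchors <- function(x) {
  swap <- x@anchor1 > x@anchor2
  tmp <- x@anchor1[swap]
  x@anchor1[swap] <- x@anchor2[swap]
  x@anchor2[swap] <- tmp
  x
}

#' Concatenate two interaction tables
#'
#' Rows of `y` follow rows of `x`; the region sets are merged (union,
#' deduplicated) and anchor indices remapped so every row still resolves
#' to exactly the same coordinates.
#'
#' @param x,y [InteractionTable-class] objects with identical metadata
#'   column names.
#' @return The combined table. Strict mode is preserved only if both
#'   inputs are strict.
#' @export
concat_interactions <- function(x, y) {
  if (!setequal(names(x@metadata), names(y@metadata))) {
    stop("metadata column names differ between the two tables",
         call. = FALSE)
  }
  nx <- length(x)
  ax <- anchors(x)
  ay <- anchors(y)
  lv <- unique(c(x@region_set@chrom_levels, y@region_set@chrom_levels))
  if (identical(lv, default_chrom_levels(lv))) lv <- NULL
  meta_y <- y@metadata[, names(x@metadata), drop = FALSE]
  # rbind of zero-column data.frames drops rows; rebuild by hand
  meta <- if (ncol(x@metadata) == 0L) {
    data.frame(matrix(nrow = nx + length(y), ncol = 0L))
  } else {
    rbind(x@metadata, meta_y)
  }
  gm <- x@global_metadata
  gm[setdiff(names(y@global_metadata), names(gm))] <-
    y@global_metadata[setdiff(names(y@global_metadata), names(gm))]
  make_interactions(rbind(ax$first, ay$first),
                    rbind(ax$second, ay$second),
                    metadata = meta,
                    strict = isTRUE(x@strict) && isTRUE(y@strict),
                    chrom_levels = lv,
                    global_metadata = gm)
}

#' Sort interactions into canonical row order
#'
#' Orders rows by `(anchor1, anchor2)` index pairs; ties keep their input
#' order (stable sort).
#'
#' @param x An [InteractionTable-class].
#' @return A list with `table` (the sorted table) and `permutation`
#'   (integer vector mapping output rows to input rows, i.e.
#'   `table == x[permutation]`).
#' @export
canonical_sort <- function(x) {
  ord <- order(x@anchor1, x@anchor2, method = "radix")
  list(table = x[ord], permutation = ord)
}

#' Flag duplicated interactions
#'
#' A row is flagged when an earlier row stores the same `(anchor1,
#' anchor2)` index pair. The comparison is on stored pairs as-is: to treat
#' `(a, b)` and `(b, a)` as the same interaction, apply [swap_anchors()]
#' first.
#'
#' @param x An [InteractionTable-class].
#' @return Logical vector, one flag per interaction.
#' @export
interaction_duplicated <- function(x) {
  duplicated(paste(x@anchor1, x@anchor2))
}

#' @describeIn InteractionTable-class subset interactions by row; repeats
#'   allowed, order significant. The region set is kept as-is.
#' @param i Row indices (integer or logical).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "InteractionTable", function(x, i, j, ..., drop = FALSE) {
  i <- seq_along(x@anchor1)[i]
  if (anyNA(i)) stop("subscript out of bounds", call. = FALSE)
  meta <- x@metadata[i, , drop = FALSE]
  rownames(meta) <- NULL
  initialize(x, anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
             metadata = meta)
})

setMethod("show", "InteractionTable", function(object) {
  n <- length(object)
  cat(sprintf("InteractionTable with %d interaction(s) over %d region(s)%s\n",
              n, length(object@region_set),
              if (isTRUE(object@strict)) " [strict]" else ""))
  if (n) {
    a <- anchors(object)
    df <- data.frame(anchor1 = region_label(a$first),
                     anchor2 = region_label(a$second))
    if (ncol(object@metadata)) df <- cbind(df, object@metadata)
    print(utils::head(df, 5L))
    if (n > 5L) cat("...\n")
  }
})

#' Convert an interaction table to a data frame
#'
#' One row per interaction with BEDPE-style coordinate columns followed by
#' the metadata columns.
#'
#' @param x An [InteractionTable-class].
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A data.frame with columns chrom1/start1/end1/chrom2/start2/end2
#'   plus metadata.
#' @export
as.data.frame.InteractionTable <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  a <- anchors(x)
  df <- data.frame(
    chrom1 = a$first$chrom, start1 = a$first$start, end1 = a$first$end,
    chrom2 = a$second$chrom, start2 = a$second$start, end2 = a$second$end,
    stringsAsFactors = FALSE
  )
  if (ncol(x@metadata)) df <- cbind(df, x@metadata)
  df
}
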