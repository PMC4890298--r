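#' @import methods
NULL

#' RegionSet: the deduplicated reference region store
#'
#' A sorted, strictly deduplicated list of genomic regions. All anchor
#' indices in an [InteractionTable-class] or [ContactMatrix-class] point
#' into a RegionSet, so each distinct coordinate is stored exactly once
#' regardless of how many interactions use it.
#'
#' The canonical order is: chromosome (lexicographic by default, or an
#' explicit `chrom_levels` ordering supplied at construction), then start,
#' then end, then strand in the order `+`, `-`, `.`.
#'
#' @slot regions data.frame with columns chrom/start/end/strand, 0-based
#'   half-open, strictly sorted and unique.
#' @slot chrom_levels character vector giving the chromosome sort order.
#' @seealso [build_region_set()]
#' @export
setClass("RegionSet", representation(
  regions = "data.frame",
  chrom_levels = "character"
))

setValidity("RegionSet", function(object) {
  df <- object@regions
  msg <- tryCatch({
    validate_regions(df)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(msg)) return(msg)
  if (!all(df$chrom %in% object@chrom_levels)) {
    return("all chromosomes must appear in chrom_levels")
  }
  if (nrow(df) > 1L) {
    if (!identical(region_order(df, object@chrom_levels), seq_len(nrow(df)))) {
      return("regions must be in canonical sorted order")
    }
    if (anyDuplicated(region_key(df))) {
      return("regions must be unique (coordinate + strand identity)")
    }
  }
  TRUE
})

#' Build a deduplicated, sorted reference region set
#'
#' Sorts the input regions into canonical order, removes duplicates
#' (coordinate + strand identity), and returns the mapping from each input
#' region to its slot in the reference set. The output is invariant under
#' permutation of the input.
#'
#' @param regions A region data frame (see [gregions()]).
#' @param chrom_levels Optional explicit chromosome ordering; defaults to
#'   lexicographic (radix) order of the chromosomes present. When supplied
#'   it must cover every chromosome in `regions` and then governs all
#'   sorting involving the resulting set.
#' @return A list with elements `region_set` (a [RegionSet-class]) and
#'   `index_map` (integer vector, `index_map[i]` is the 1-based position of
#'   input region `i` in the reference set).
#' @examples
#' r <- gregions(c("chr1", "chr1", "chr1"), c(20, 1, 20), c(30, 10, 30))
#' rs <- build_region_set(r)
#' rs$index_map  # 2 1 2
#' @export
build_region_set <- function(regions, chrom_levels = NULL) {
  df <- region_core(validate_regions(regions))
  if (is.null(chrom_levels)) {
    chrom_levels <- default_chrom_levels(df$chrom)
  } else {
    chrom_levels <- as.character(chrom_levels)
    missing_chr <- setdiff(df$chrom, chrom_levels)
    if (length(missing_chr)) {
      stop(sprintf("chrom_levels is missing chromosome '%s'", missing_chr[1]),
           call. = FALSE)
    }
  }
  keep <- !duplicated(region_key(df))
  uniq <- df[keep, , drop = FALSE]
  uniq <- uniq[region_order(uniq, chrom_levels), , drop = FALSE]
  rownames(uniq) <- NULL
  rs <- new("RegionSet", regions = uniq, chrom_levels = chrom_levels)
  list(
    region_set = rs,
    index_map = match(region_key(df), region_key(uniq))
  )
}

#' Regions stored in an object
#'
#' @param x A RegionSet, InteractionTable, AssaySet or ContactMatrix.
#' @return The reference region data frame.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname regions
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' @describeIn RegionSet-class number of reference regions.
#' @param x A RegionSet.
#' @export
setMethod("length", "RegionSet", function(x) nrow(x@regions))

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet with %d regions on %d chromosome(s)\n",
              nrow(object@regions), length(unique(object@regions$chrom))))
  if (nrow(object@regions)) {
    print(utils::head(object@regions, 5L))
    if (nrow(object@regions) > 5L) cat("...\n")
  }
})
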