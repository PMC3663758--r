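#' Accessors for methbind classes
#'
#' @param x a methbind object.
#' @name methbind-accessors
NULL

#' @describeIn methbind-accessors summit tag heights of a `PeakSet`.
#' @export
setGeneric("peakHeights", function(x) standardGeneric("peakHeights"))

#' @describeIn methbind-accessors 1-based ranks (descending height) of a
#'   `PeakSet`.
#' @export
setGeneric("peakRanks", function(x) standardGeneric("peakRanks"))

#' @describeIn methbind-accessors provenance string of a `PeakSet`.
#' @export
setGeneric("peakSource", function(x) standardGeneric("peakSource"))

#' @describeIn methbind-accessors common peaks (on the first set's
#'   coordinates) of an `OverlapResult`, or a named list of the four
#'   partitions.
#' @export
setGeneric("commonPeaks", function(x) standardGeneric("commonPeaks"))

#' @describeIn methbind-accessors unique (non-overlapping) peaks of an
#'   `OverlapResult`, as a named list with elements `a` and `b`.
#' @export
setGeneric("uniquePeaks", function(x) standardGeneric("uniquePeaks"))

#' @describeIn methbind-accessors per-bin values of a `BinnedProfile`.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @describeIn methbind-accessors per-bin contributing-observation counts of
#'   a `BinnedProfile`.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @describeIn methbind-accessors 0-based offsets of the left edge of each
#'   bin of a `BinnedProfile`, relative to the anchor midpoint.
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

setMethod("peakHeights", "PeakSet", function(x) mcols(x)$height)
setMethod("peakRanks", "PeakSet", function(x) mcols(x)$rank)
setMethod("peakSource", "PeakSet", function(x) metadata(x)$source)

setMethod("commonPeaks", "OverlapResult", function(x)
    list(a = x@common_a, b = x@common_b))
setMethod("uniquePeaks", "OverlapResult", function(x)
    list(a = x@unique_a, b = x@unique_b))

setMethod("profileValues", "BinnedProfile", function(x) x@values)
setMethod("profileCounts", "BinnedProfile", function(x) x@counts)
setMethod("profileOffsets", "BinnedProfile", function(x)
    seq(-x@halfwidth, x@halfwidth - x@binSize, by = x@binSize))
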