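#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqnames seqlevels
#' @importFrom Biostrings DNAStringSet readDNAStringSet subseq
#' @importFrom jsonlite write_json
NULL

#' PeakSet: a ranked set of scored ChIP-seq peaks
#'
#' A `PeakSet` is a [GenomicRanges::GRanges] with two required metadata
#' columns: `height`, the tag count at the peak summit, and `rank`, the
#' 1-based rank by descending height (ties broken by chromosome then start).
#' The provenance of the set (cell type, replicate) is kept in
#' `metadata(x)$source`.
#'
#' Coordinates follow the usual GRanges convention (1-based, closed); BED
#' input/output converts to and from the 0-based half-open BED dialect.
#'
#' @slot .Data inherited GRanges representation.
#' @seealso [PeakSet()], [readPeaks()], [overlapPeakSets()]
#' @exportClass PeakSet
setClass("PeakSet", contains = "GRanges")

.validPeakSet <- function(object) {
    msg <- character()
    mc <- mcols(object)
    if (!all(c("height", "rank") %in% colnames(mc)))
        return("metadata columns 'height' and 'rank' are required")
    if (length(object)) {
        if (any(is.na(mc$height)) || any(mc$height < 0))
            msg <- c(msg, "'height' must be non-negative")
        if (!setequal(mc$rank, seq_along(object)))
            msg <- c(msg, "'rank' must be a permutation of 1..n")
        else {
            ord <- order(mc$rank)
            h <- mc$height[ord]
            if (is.unsorted(rev(h)))
                msg <- c(msg, "'rank' must be consistent with descending height")
        }
        key <- paste(seqnames(object), start(object), end(object))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, start, end) peaks are not allowed")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PeakSet", .validPeakSet)

#' Construct a PeakSet from a GRanges of scored peaks
#'
#' Ranks are (re)assigned by descending `height`, breaking ties by
#' chromosome name then start coordinate, so the result always satisfies the
#' `PeakSet` validity contract.
#'
#' @param gr a `GRanges` with a numeric `height` metadata column (or a
#'   `height` argument).
#' @param height optional numeric vector of summit tag heights, used when
#'   `gr` lacks a `height` column.
#' @param source free-text provenance (cell type, replicate id).
#' @return a `PeakSet`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 301), c(200, 400)))
#' PeakSet(gr, height = c(10, 40), source = "toy")
#' @export
PeakSet <- function(gr, height = NULL, source = NA_character_) {
    if (!is(gr, "GRanges"))
        stop("'gr' must be a GRanges")
    if (!is.null(height))
        mcols(gr)$height <- height
    if (is.null(mcols(gr)$height))
        stop("peaks need a 'height' metadata column or a 'height' argument")
    mcols(gr)$height <- as.numeric(mcols(gr)$height)
    mcols(gr)$rank <- .assignRanks(gr)
    out <- as(gr, "PeakSet")
    metadata(out)$source <- source
    validObject(out)
    out
}

# rank 1 = tallest; ties by (chrom, start) lexicographic
.assignRanks <- function(gr) {
    ord <- order(-mcols(gr)$height, as.character(seqnames(gr)), start(gr))
    rk <- integer(length(gr))
    rk[ord] <- seq_along(gr)
    rk
}

setMethod("show", "PeakSet", function(object) {
    src <- metadata(object)$source
    cat("PeakSet with ", length(object), " peaks",
        if (!is.null(src) && !is.na(src)) paste0(" [", src, "]"), "\n", sep = "")
    if (length(object)) {
        cat("  median height: ", stats::median(peakHeights(object)),
            "; height range: [", min(peakHeights(object)), ", ",
            max(peakHeights(object)), "]\n", sep = "")
    }
    methods::callNextMethod()
})

#' OverlapResult: common and unique peaks between two peak sets
#'
#' Partition of two peak sets A and B by whether each peak shares at least
#' `minOverlap` base pairs with some peak of the other set.
#'
#' @slot common_a,unique_a peaks of A that do / do not overlap B.
#' @slot common_b,unique_b peaks of B that do / do not overlap A.
#' @slot minOverlap minimum shared base pairs used as the overlap criterion.
#' @exportClass OverlapResult
setClass("OverlapResult",
    representation(common_a = "PeakSet", unique_a = "PeakSet",
                   common_b = "PeakSet", unique_b = "PeakSet",
                   minOverlap = "integer"))

setValidity("OverlapResult", function(object) {
    if (object@minOverlap < 1L)
        return("minOverlap must be >= 1")
    TRUE
})

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult (>= ", object@minOverlap, " bp shared)\n", sep = "")
    cat("  A: ", length(object@common_a), " common + ",
        length(object@unique_a), " unique = ",
        length(object@common_a) + length(object@unique_a), "\n", sep = "")
    cat("  B: ", length(object@common_b), " common + ",
        length(object@unique_b), " unique = ",
        length(object@common_b) + length(object@unique_b), "\n", sep = "")
})

#' ReproducibilityReport: ENCODE-style replicate concordance
#'
#' Result of the 40% overlap rule: both replicates are truncated (by rank) to
#' the smaller peak count, and the top 40% of one truncated replicate is
#' overlapped against the whole of the other, reciprocally. A pair passes
#' when the original set sizes are within a factor of two and both overlap
#' percentages reach 80%.
#'
#' @slot pct_forward percent of the top 40% of truncated replicate 1
#'   overlapping truncated replicate 2.
#' @slot pct_reciprocal the symmetric percentage.
#' @slot count_ratio larger original peak count over smaller.
#' @slot passes_encode logical; `count_ratio <= 2` and both percentages
#'   `>= 80`.
#' @exportClass ReproducibilityReport
setClass("ReproducibilityReport",
    representation(pct_forward = "numeric", pct_reciprocal = "numeric",
                   count_ratio = "numeric", passes_encode = "logical"))

setValidity("ReproducibilityReport", function(object) {
    msg <- character()
    p <- c(object@pct_forward, object@pct_reciprocal)
    if (any(p < 0 | p > 100))
        msg <- c(msg, "percentages must lie in [0, 100]")
    if (object@count_ratio < 1)
        msg <- c(msg, "count_ratio must be >= 1")
    want <- object@count_ratio <= 2 && all(p >= 80)
    if (!identical(want, object@passes_encode))
        msg <- c(msg, "passes_encode inconsistent with its definition")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ReproducibilityReport", function(object) {
    cat(sprintf("ReproducibilityReport: %.1f%% (%.1f%% reciprocal), count ratio %.2f -> %s\n",
                object@pct_forward, object@pct_reciprocal, object@count_ratio,
                if (object@passes_encode) "PASS" else "FAIL"))
})

#' BinnedProfile: binned average signal around a set of anchors
#'
#' Shared representation for tag-density meta-profiles and methylation
#' meta-profiles. Offsets are 0-based distances from the anchor midpoint,
#' covering the half-open window `[-halfwidth, +halfwidth)` in bins of
#' `binSize` bp; `values[i]` is the per-bin statistic and `counts[i]` the
#' number of contributing observations (bins with `counts == 0` carry `NA`,
#' which is distinct from a measured 0).
#'
#' @slot halfwidth half-window size in bp.
#' @slot binSize bin width in bp; must divide `2 * halfwidth`.
#' @slot values numeric per-bin statistic.
#' @slot counts integer per-bin contributing-observation count.
#' @slot nAnchors number of anchors profiled.
#' @slot kind `"tag_density"` or `"methylation"`.
#' @slot nTags total tags in the dataset (tag-density profiles only).
#' @exportClass BinnedProfile
setClass("BinnedProfile",
    representation(halfwidth = "integer", binSize = "integer",
                   values = "numeric", counts = "integer",
                   nAnchors = "integer", kind = "character",
                   nTags = "numeric"))

setValidity("BinnedProfile", function(object) {
    msg <- character()
    nb <- 2L * object@halfwidth / object@binSize
    if (nb != as.integer(nb))
        msg <- c(msg, "binSize must divide 2 * halfwidth")
    if (length(object@values) != nb || length(object@counts) != nb)
        msg <- c(msg, sprintf("profile must have %d bins", as.integer(nb)))
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (any(!is.na(object@values) & object@kind == "tag_density" &
            object@values < 0))
        msg <- c(msg, "tag-density values must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BinnedProfile", function(object) {
    cat("BinnedProfile (", object@kind, "): +/-", object@halfwidth,
        " bp in ", length(object@values), " bins of ", object@binSize,
        " bp over ", object@nAnchors, " anchors\n", sep = "")
    v <- object@values[!is.na(object@values)]
    if (length(v))
        cat(sprintf("  value range: [%.4g, %.4g]\n", min(v), max(v)))
})
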