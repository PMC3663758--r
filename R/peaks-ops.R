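#' Overlap two peak sets
#'
#' A peak of A is "common" when it shares at least `minOverlap` base pairs
#' with at least one peak of B on the same chromosome (and vice versa).
#' Abutting intervals share no base and do not overlap.
#'
#' @param a,b [PeakSet] objects.
#' @param minOverlap minimum shared base pairs (default 1).
#' @return an [OverlapResult].
#' @examples
#' a <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)),
#'              height = 10)
#' b <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300)),
#'              height = 10)
#' overlapPeakSets(a, b)  # 1 bp shared at position 200
#' @export
overlapPeakSets <- function(a, b, minOverlap = 1L) {
    if (minOverlap < 1L)
        stop("'minOverlap' must be >= 1")
    inB <- .olap(a, b, minoverlap = minOverlap)
    inA <- .olap(b, a, minoverlap = minOverlap)
    new("OverlapResult",
        common_a = .subsetPeaks(a, inB), unique_a = .subsetPeaks(a, !inB),
        common_b = .subsetPeaks(b, inA), unique_b = .subsetPeaks(b, !inA),
        minOverlap = as.integer(minOverlap))
}

#' Derive high-confidence peaks present in both replicates
#'
#' High-confidence peaks are peaks present (by overlap) in both biological
#' replicates, regardless of height. When a merged-replicate call set is
#' supplied the result consists of merged peaks overlapping at least one
#' peak of each replicate, carrying the merged heights; otherwise replicate
#' 1 peaks overlapping replicate 2 are returned.
#'
#' @param rep1,rep2 replicate [PeakSet]s.
#' @param merged optional merged-replicate [PeakSet] providing coordinates
#'   and heights for the result.
#' @param minOverlap minimum shared base pairs.
#' @return a [PeakSet]; `metadata(x)$hc_mode` records whether merged or
#'   replicate-1 coordinates were used.
#' @export
deriveHighConfidence <- function(rep1, rep2, merged = NULL, minOverlap = 1L) {
    if (is.null(merged)) {
        keep <- .olap(rep1, rep2, minoverlap = minOverlap)
        out <- .subsetPeaks(rep1, keep)
        metadata(out)$hc_mode <- "rep1"
    } else {
        keep <- .olap(merged, rep1, minoverlap = minOverlap) &
                .olap(merged, rep2, minoverlap = minOverlap)
        out <- .subsetPeaks(merged, keep)
        metadata(out)$hc_mode <- "merged"
    }
    out
}

#' Assess replicate reproducibility by the ENCODE 40% overlap rule
#'
#' Both replicates are truncated (by rank) to the smaller peak count; the
#' top 40% of truncated replicate 1 is overlapped against the whole of
#' truncated replicate 2, and reciprocally. The pair passes ENCODE
#' standards when the original counts are within a factor of two and both
#' percentages reach 80%.
#'
#' @param rep1,rep2 non-empty replicate [PeakSet]s.
#' @param fraction top fraction compared (default 0.4).
#' @param minOverlap minimum shared base pairs.
#' @return a [ReproducibilityReport].
#' @export
assessReproducibility <- function(rep1, rep2, fraction = 0.4,
                                  minOverlap = 1L) {
    if (length(rep1) == 0L || length(rep2) == 0L)
        stop("replicates must be non-empty")
    n <- min(length(rep1), length(rep2))
    t1 <- .subsetPeaks(rep1, peakRanks(rep1) <= n)
    t2 <- .subsetPeaks(rep2, peakRanks(rep2) <= n)
    k <- as.integer(ceiling(fraction * n))
    top1 <- .subsetPeaks(t1, peakRanks(t1) <= k)
    top2 <- .subsetPeaks(t2, peakRanks(t2) <= k)
    pf <- 100 * mean(.olap(top1, t2, minoverlap = minOverlap))
    pr <- 100 * mean(.olap(top2, t1, minoverlap = minOverlap))
    ratio <- max(length(rep1), length(rep2)) / n
    new("ReproducibilityReport",
        pct_forward = pf, pct_reciprocal = pr, count_ratio = ratio,
        passes_encode = ratio <= 2 && pf >= 80 && pr >= 80)
}

#' Select the top fraction of a peak set by rank
#'
#' Keeps the `ceiling(fraction * n)` highest-ranked (tallest) peaks, the
#' selection used e.g. to retain the top 20% of Pol2 peaks as robust
#' promoter-bound peaks.
#'
#' @param peaks a [PeakSet].
#' @param fraction proportion in (0, 1].
#' @return a [PeakSet].
#' @export
selectTopFraction <- function(peaks, fraction) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]")
    k <- as.integer(ceiling(fraction * length(peaks)))
    .subsetPeaks(peaks, peakRanks(peaks) <= k)
}

#' Rank curve: tag height versus ranked peak number
#'
#' @param peaks a [PeakSet].
#' @return a `data.frame` with columns `rank` and `height`, height
#'   non-increasing in rank.
#' @export
rankCurve <- function(peaks) {
    ord <- order(peakRanks(peaks))
    data.frame(rank = peakRanks(peaks)[ord], height = peakHeights(peaks)[ord])
}

#' Remove peaks overlapping a blacklist (e.g. amplified regions)
#'
#' Drops every peak sharing at least one base pair with any blacklist
#' interval, the filter applied to cancer-cell peak sets where copy-number
#' amplified regions generate artifactual peaks.
#'
#' @param peaks a [PeakSet].
#' @param blacklist a `GRanges` of intervals to exclude.
#' @return the retained [PeakSet]; the removed peaks are attached as
#'   `metadata(x)$removed`.
#' @export
filterBlacklist <- function(peaks, blacklist) {
    hit <- .olap(peaks, blacklist, minoverlap = 1L)
    out <- .subsetPeaks(peaks, !hit)
    metadata(out)$removed <- .subsetPeaks(peaks, hit)
    out
}

#' Classify peaks as promoter proximal or distal
#'
#' A peak is promoter proximal when its midpoint lies within `window` bp
#' (inclusive) of any transcription start site; all other peaks are distal.
#' Each peak is additionally annotated with its nearest TSS, the signed
#' strand-aware distance to it (positive = downstream of the gene's
#' direction of transcription), and the gene id.
#'
#' @param peaks a [PeakSet].
#' @param tss a width-1 `GRanges` of TSS positions with strand and a
#'   `gene_id` metadata column (see [readTss()]).
#' @param window proximal window half-width in bp (default 1000).
#' @return a list with [PeakSet] elements `proximal` and `distal`, and
#'   `annotation`, a `data.frame` (one row per input peak, in input order)
#'   with columns `midpoint0`, `gene_id`, `distance`, `proximal`.
#' @export
classifyLocation <- function(peaks, tss, window = 1000L) {
    if (window <= 0L)
        stop("'window' must be positive")
    n <- length(peaks)
    ann <- data.frame(midpoint0 = .midpoint0(peaks),
                      gene_id = NA_character_,
                      distance = NA_real_,
                      proximal = FALSE)
    if (length(tss) == 0L) {
        warning("empty TSS list: all peaks classified distal")
        return(list(proximal = .subsetPeaks(peaks, logical(n)),
                    distal = peaks, annotation = ann))
    }
    pchr <- as.character(seqnames(peaks))
    tchr <- as.character(seqnames(tss))
    tss0 <- start(tss) - 1L
    tstr <- as.character(strand(tss))
    gid <- mcols(tss)$gene_id
    for (i in seq_len(n)) {
        j <- which(tchr == pchr[i])
        if (!length(j)) next
        d <- ann$midpoint0[i] - tss0[j]
        jj <- j[which.min(abs(d))]
        dmin <- ann$midpoint0[i] - tss0[jj]
        ann$gene_id[i] <- gid[jj]
        ann$distance[i] <- if (tstr[jj] == "-") -dmin else dmin
        ann$proximal[i] <- any(abs(d) <= window)
    }
    list(proximal = .subsetPeaks(peaks, ann$proximal),
         distal = .subsetPeaks(peaks, !ann$proximal),
         annotation = ann)
}
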