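# Bisulfite-call handling: ingestion, WGBS+RRBS merging, coverage
# filtering, anchored methylation meta-profiles, per-CGCG-motif methylation
# and its low/medium/high classification.
#
# CpG calls are width-1 GRanges positioned on the plus-strand cytosine of
# the CpG, with metadata columns meth_reads, total_reads and beta (percent).

#' Build a CpG call set
#'
#' @param chrom chromosome names.
#' @param pos0 0-based positions of the plus-strand CpG cytosines.
#' @param meth methylated read counts.
#' @param total total read counts (>= meth, >= 1).
#' @return a width-1 `GRanges` with metadata columns `meth_reads`,
#'   `total_reads` and `beta` (percent methylation).
#' @export
cpgCalls <- function(chrom, pos0, meth, total) {
    if (any(total < 1L)) stop("total_reads must be >= 1")
    if (any(meth < 0L | meth > total))
        stop("meth_reads must lie in [0, total_reads]")
    gr <- .gr0(chrom, pos0, pos0 + 1L)
    mcols(gr)$meth_reads <- as.integer(meth)
    mcols(gr)$total_reads <- as.integer(total)
    mcols(gr)$beta <- 100 * meth / total
    sort(gr)
}

#' Read bisulfite calls from a tabular export
#'
#' Two layouts are supported and auto-detected by column count: a
#' bedGraph-like file (chrom, start, end, beta%, meth_reads, total_reads;
#' 6 columns) and a two-count file (chrom, pos, strand, meth_reads,
#' total_reads; 5 columns). Calls on the minus-strand cytosine of a CpG
#' are collapsed onto the plus-strand position (pos - 1) by summing counts,
#' so downstream analyses see one record per CpG.
#'
#' @param path input path; `#`-comment lines are skipped.
#' @return a CpG call `GRanges` (see [cpgCalls()]).
#' @export
readBisulfite <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#",
                            colClasses = NA, stringsAsFactors = FALSE)
    if (ncol(df) >= 6L && !df[[3L]][1L] %in% c("+", "-")) {
        chrom <- df[[1L]]; pos0 <- as.integer(df[[2L]])
        meth <- as.integer(df[[5L]]); total <- as.integer(df[[6L]])
        strand <- rep("+", nrow(df))
    } else if (ncol(df) >= 5L) {
        chrom <- df[[1L]]; pos0 <- as.integer(df[[2L]])
        strand <- as.character(df[[3L]])
        meth <- as.integer(df[[4L]]); total <- as.integer(df[[5L]])
    } else {
        stop("'", path, "' is neither a 6-column bedGraph-like nor a ",
             "5-column two-count bisulfite table")
    }
    pos0[strand == "-"] <- pos0[strand == "-"] - 1L
    agg <- stats::aggregate(cbind(meth, total),
                            by = list(chrom = chrom, pos0 = pos0), FUN = sum)
    cpgCalls(agg$chrom, agg$pos0, agg$meth, agg$total)
}

#' Write bisulfite calls as a bedGraph-like table
#'
#' Columns: chrom, pos0, pos0+1, beta%, meth_reads, total_reads.
#'
#' @param calls a CpG call `GRanges`.
#' @param path output path.
#' @export
writeBisulfite <- function(calls, path) {
    df <- data.frame(chrom = as.character(seqnames(calls)),
                     start = start(calls) - 1L, end = start(calls),
                     beta = round(mcols(calls)$beta, 4),
                     meth = mcols(calls)$meth_reads,
                     total = mcols(calls)$total_reads)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Merge two bisulfite call sets (e.g. WGBS + RRBS)
#'
#' Records at the same (chrom, position) are merged by summing methylated
#' and total read counts and recomputing beta, the information-preserving
#' way to combine platforms for higher genomic coverage; positions covered
#' by only one set pass through unchanged.
#'
#' @param a,b CpG call `GRanges` (see [cpgCalls()]), same genome build.
#' @param mode `"sum"` (default) or `"prefer_a"`, which keeps `a`'s record
#'   wherever both sets cover a position.
#' @return a merged CpG call `GRanges`.
#' @export
mergeCallSets <- function(a, b, mode = c("sum", "prefer_a")) {
    mode <- match.arg(mode)
    if (mode == "prefer_a") {
        keep <- !.olap(b, a)
        return(sort(c(a, b[keep])))
    }
    chrom <- c(as.character(seqnames(a)), as.character(seqnames(b)))
    if (length(chrom) == 0L)
        return(cpgCalls(character(0), integer(0), integer(0), integer(0)))
    pos0 <- c(start(a), start(b)) - 1L
    meth <- c(mcols(a)$meth_reads, mcols(b)$meth_reads)
    total <- c(mcols(a)$total_reads, mcols(b)$total_reads)
    agg <- stats::aggregate(cbind(meth, total),
                            by = list(chrom = chrom, pos0 = pos0), FUN = sum)
    cpgCalls(agg$chrom, agg$pos0, agg$meth, agg$total)
}

#' Filter CpG calls by sequencing coverage
#'
#' Keeps CpGs with at least `minTotal` total reads (default 3, the minimum
#' coverage used for all methylation analyses).
#'
#' @param calls a CpG call `GRanges`.
#' @param minTotal minimum total read count (>= 1).
#' @return the filtered `GRanges`.
#' @export
filterCoverage <- function(calls, minTotal = 3L) {
    if (minTotal < 1L) stop("'minTotal' must be >= 1")
    calls[mcols(calls)$total_reads >= minTotal]
}

#' Methylation meta-profile around anchors
#'
#' Averages percent methylation of covered CpGs in offset bins around the
#' midpoints of a set of anchor intervals. Offsets cover the half-open
#' window `[-halfwidth, +halfwidth)`; a CpG at offset `d` from an anchor
#' midpoint contributes its beta to bin `floor((d + halfwidth) / binSize)`.
#' Bins without any contributing CpG are `NA`, distinct from a measured 0%.
#'
#' @param anchors a `GRanges` (or [PeakSet]) of anchor intervals; the
#'   0-based midpoint of each is the profile center.
#' @param calls a coverage-filtered CpG call `GRanges`.
#' @param halfwidth half-window in bp (default 250).
#' @param binSize bin width in bp (default 10); must divide
#'   `2 * halfwidth`.
#' @return a [BinnedProfile] of kind `"methylation"` (values in percent).
#' @export
profileMethylation <- function(anchors, calls, halfwidth = 250L,
                               binSize = 10L) {
    halfwidth <- as.integer(halfwidth); binSize <- as.integer(binSize)
    if ((2L * halfwidth) %% binSize != 0L)
        stop("'binSize' must divide 2 * halfwidth")
    nbins <- (2L * halfwidth) %/% binSize
    sums <- numeric(nbins); cnts <- integer(nbins)
    mid0 <- .midpoint0(anchors)
    win <- .gr0(as.character(seqnames(anchors)),
                pmax(mid0 - halfwidth, 0L), mid0 + halfwidth)
    ov <- findOverlaps(calls, win)
    if (length(ov)) {
        off <- (start(calls)[queryHits(ov)] - 1L) - mid0[subjectHits(ov)]
        keep <- off >= -halfwidth & off < halfwidth
        off <- off[keep]
        beta <- mcols(calls)$beta[queryHits(ov)][keep]
        bin <- (off + halfwidth) %/% binSize + 1L
        sums <- as.numeric(tapply(beta, factor(bin, levels = seq_len(nbins)),
                                  sum, default = 0))
        cnts <- as.integer(tapply(beta, factor(bin, levels = seq_len(nbins)),
                                  length, default = 0L))
    }
    vals <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), NA_real_)
    new("BinnedProfile", halfwidth = halfwidth, binSize = binSize,
        values = vals, counts = cnts, nAnchors = length(anchors),
        kind = "methylation", nTags = NA_real_)
}

#' Classify a beta value as low, medium or high methylation
#'
#' Low is below `lowMax` percent, high above `highMin` percent, medium the
#' closed interval in between (the boundaries 20 and 60 themselves are
#' medium).
#'
#' @param beta percent methylation in \[0, 100\] (vectorised).
#' @param lowMax low/medium boundary (default 20).
#' @param highMin medium/high boundary (default 60).
#' @return character vector in `c("low", "medium", "high")`.
#' @examples
#' classifyBeta(c(19.999, 20, 60, 60.001))  # low medium medium high
#' @export
classifyBeta <- function(beta, lowMax = 20, highMin = 60) {
    if (any(is.na(beta)) || any(beta < 0 | beta > 100))
        stop("'beta' must lie in [0, 100]")
    if (!(0 < lowMax && lowMax < highMin && highMin < 100))
        stop("class boundaries must satisfy 0 < lowMax < highMin < 100")
    ifelse(beta < lowMax, "low", ifelse(beta > highMin, "high", "medium"))
}

#' Per-motif methylation from covered CpGs
#'
#' For each motif occurrence (e.g. a CGCG hit, which spans two CpGs) the
#' covered CpGs falling inside the motif interval are collected; the
#' motif's aggregate beta is their unweighted mean (or coverage-weighted
#' with `weighted = TRUE`) and is classified low/medium/high. Motifs with
#' no covered CpG are classed `"uncovered"`.
#'
#' @param hits a hit `data.frame` (columns `chrom`, `start0`, `end0`; see
#'   [annotateMotifPresence()]) or a `GRanges` of motif intervals.
#' @param calls a coverage-filtered CpG call `GRanges`.
#' @param weighted use a coverage-weighted mean (default FALSE).
#' @param lowMax,highMin class boundaries passed to [classifyBeta()].
#' @return a `data.frame` with one row per motif: `chrom`, `start0`,
#'   `end0`, `n_cpg` covered CpGs, `beta` aggregate (NA when uncovered),
#'   `class`.
#' @export
motifMethylation <- function(hits, calls, weighted = FALSE,
                             lowMax = 20, highMin = 60) {
    gr <- if (is(hits, "GRanges")) hits
          else .gr0(hits$chrom, hits$start0, hits$end0)
    n <- length(gr)
    out <- data.frame(chrom = as.character(seqnames(gr)),
                      start0 = start(gr) - 1L, end0 = end(gr),
                      n_cpg = 0L, beta = NA_real_,
                      class = "uncovered")
    if (n == 0L) return(out)
    ov <- findOverlaps(calls, gr)
    for (i in seq_len(n)) {
        j <- queryHits(ov)[subjectHits(ov) == i]
        if (!length(j)) next
        b <- mcols(calls)$beta[j]
        w <- if (weighted) mcols(calls)$total_reads[j] else rep(1, length(j))
        out$n_cpg[i] <- length(j)
        out$beta[i] <- sum(b * w) / sum(w)
        out$class[i] <- classifyBeta(out$beta[i], lowMax, highMin)
    }
    out
}

#' Pair motif methylation with the score of the containing peak
#'
#' Each covered motif is assigned to the peak that contains it (a motif
#' lying outside every peak is dropped; if peaks overlap, the tallest
#' containing peak is used) and exported as (peak height, peak rank, motif
#' beta) rows for rank-versus-methylation plots.
#'
#' @param peaks a [PeakSet].
#' @param motifMeth a `data.frame` from [motifMethylation()].
#' @return a `data.frame` with columns `peak`, `height`, `rank`, `beta`.
#' @export
methylationVsRank <- function(peaks, motifMeth) {
    covered <- motifMeth[!is.na(motifMeth$beta), , drop = FALSE]
    if (!nrow(covered))
        return(data.frame(peak = integer(0), height = numeric(0),
                          rank = integer(0), beta = numeric(0)))
    gr <- .gr0(covered$chrom, covered$start0, covered$end0)
    ov <- findOverlaps(gr, peaks, type = "within")
    if (!length(ov))
        return(data.frame(peak = integer(0), height = numeric(0),
                          rank = integer(0), beta = numeric(0)))
    df <- data.frame(motif = queryHits(ov), peak = subjectHits(ov),
                     h = peakHeights(peaks)[subjectHits(ov)])
    df <- df[order(df$motif, -df$h), ]
    df <- df[!duplicated(df$motif), ]
    data.frame(peak = df$peak,
               height = peakHeights(peaks)[df$peak],
               rank = peakRanks(peaks)[df$peak],
               beta = covered$beta[df$motif])
}

#' Box-plot summary of motif methylation measured in another cell type
#'
#' Summarises the distribution of covered motif betas, the statistic used
#' to compare methylation of cell-type-unique binding sites across cell
#' lines.
#'
#' @param motifMeth a `data.frame` from [motifMethylation()] computed
#'   against the other cell type's bisulfite calls.
#' @return a list with `n` covered motifs and `stats`, the five-number
#'   summary (min, Q1, median, Q3, max) or `NULL` when nothing is covered.
#' @export
crossCellMethylation <- function(motifMeth) {
    b <- motifMeth$beta[!is.na(motifMeth$beta)]
    if (!length(b)) return(list(n = 0L, stats = NULL))
    q <- stats::quantile(b, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    list(n = length(b),
         stats = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                   max = q[5]))
}
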