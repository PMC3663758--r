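# Cross-cell-type binding comparison: common vs cell-type-specific peaks,
# motif-presence partitioning, and expression by binding class.

#' Compare high-confidence peak sets from two cell types
#'
#' Overlaps the two sets to obtain peaks common to both cell types
#' (reported on cell A's coordinates, with cell B's version alongside) and
#' the cell-type-specific remainders, plus the per-subset median summit
#' height and, when TSS annotation is supplied, the per-subset promoter
#' proximal/distal split.
#'
#' @param hcA,hcB high-confidence [PeakSet]s for the two cell types.
#' @param tss optional TSS `GRanges` (see [readTss()]) for the
#'   proximal/distal split.
#' @param window proximal window in bp (default 1000).
#' @param minOverlap minimum shared base pairs.
#' @return a list: `common` (A coordinates), `common_b`, `unique_a`,
#'   `unique_b` [PeakSet]s; `median_height`, named medians per subset; and
#'   `location`, a per-subset data.frame of proximal/distal counts (NULL
#'   without `tss`).
#' @export
compareCellTypes <- function(hcA, hcB, tss = NULL, window = 1000L,
                             minOverlap = 1L) {
    ov <- overlapPeakSets(hcA, hcB, minOverlap = minOverlap)
    subsets <- list(common = ov@common_a, common_b = ov@common_b,
                    unique_a = ov@unique_a, unique_b = ov@unique_b)
    med <- vapply(subsets, function(p)
        if (length(p)) stats::median(peakHeights(p)) else NA_real_, 0)
    loc <- NULL
    if (!is.null(tss)) {
        loc <- do.call(rbind, lapply(names(subsets), function(nm) {
            p <- subsets[[nm]]
            if (!length(p))
                return(data.frame(subset = nm, proximal = 0L, distal = 0L))
            cl <- classifyLocation(p, tss, window)
            data.frame(subset = nm, proximal = length(cl$proximal),
                       distal = length(cl$distal))
        }))
    }
    c(subsets, list(median_height = med, location = loc))
}

#' Partition peaks by motif presence
#'
#' Splits a peak set into peaks that contain at least one exact IUPAC match
#' to the motif within the peak interval and peaks that lack one.
#'
#' @param peaks a [PeakSet].
#' @param genome a named `DNAStringSet`.
#' @param motif an IUPAC pattern (single string).
#' @param bothStrands scan both strands (default TRUE).
#' @return a list with [PeakSet]s `with_motif` and `without_motif` and the
#'   `fraction` of peaks carrying the motif.
#' @export
partitionByMotif <- function(peaks, genome, motif, bothStrands = TRUE) {
    if (length(peaks) == 0L)
        return(list(with_motif = peaks, without_motif = peaks,
                    fraction = NaN))
    ann <- annotateMotifPresence(peaks, genome, c(m = motif),
                                 bothStrands = bothStrands)
    has <- ann$presence[, 1L]
    list(with_motif = .subsetPeaks(peaks, has),
         without_motif = .subsetPeaks(peaks, !has),
         fraction = mean(has))
}

#' Expression of gene groups defined by binding class
#'
#' Given the gene groups nearest to common, A-unique and B-unique binding
#' sites and per-gene RPKM tables for both cell types, computes a
#' five-number summary per group x cell type and pairwise Mann-Whitney
#' tests between groups within each cell type.
#'
#' @param groups named list of character vectors of gene ids, e.g.
#'   `list(common = ..., unique_a = ..., unique_b = ...)`.
#' @param rpkmA,rpkmB expression `data.frame`s (see [expressionTable()])
#'   for cell types A and B.
#' @return a list with `summary`, a data.frame (group, cell, n, min, q1,
#'   median, q3, max), and `tests`, a data.frame of pairwise Mann-Whitney
#'   results per cell (NA p for groups with < 2 values).
#' @export
expressionByBindingClass <- function(groups, rpkmA, rpkmB) {
    pull <- function(tab, genes) tab$rpkm[match(genes, tab$gene_id)]
    cells <- list(A = rpkmA, B = rpkmB)
    rows <- list(); tests <- list()
    for (cell in names(cells)) {
        vals <- lapply(groups, function(g) {
            v <- pull(cells[[cell]], g)
            v[!is.na(v)]
        })
        for (g in names(vals)) {
            v <- vals[[g]]
            if (length(v)) {
                q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
                rows[[length(rows) + 1L]] <- data.frame(
                    group = g, cell = cell, n = length(v), min = q[1],
                    q1 = q[2], median = q[3], q3 = q[4], max = q[5])
            } else {
                rows[[length(rows) + 1L]] <- data.frame(
                    group = g, cell = cell, n = 0L, min = NA, q1 = NA,
                    median = NA, q3 = NA, max = NA)
            }
        }
        pairs <- utils::combn(names(vals), 2L, simplify = FALSE)
        for (pr in pairs) {
            x <- vals[[pr[1L]]]; y <- vals[[pr[2L]]]
            if (length(x) >= 2L && length(y) >= 2L) {
                mw <- mannWhitney(x, y)
                tests[[length(tests) + 1L]] <- data.frame(
                    cell = cell, group1 = pr[1L], group2 = pr[2L],
                    U = mw$U, p.value = mw$p.value)
            } else {
                warning("group '", pr[1L], "' vs '", pr[2L], "' in cell ",
                        cell, ": too few values, test skipped")
                tests[[length(tests) + 1L]] <- data.frame(
                    cell = cell, group1 = pr[1L], group2 = pr[2L],
                    U = NA_real_, p.value = NA_real_)
            }
        }
    }
    list(summary = do.call(rbind, rows), tests = do.call(rbind, tests))
}
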