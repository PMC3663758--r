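# Union-exon gene models, RPKM quantification and rank-based group
# comparison of expression.

#' Build union-exon gene models
#'
#' Combines all transcripts of each gene into a single model whose exons
#' are the union of the transcript exons (overlapping or abutting exons are
#' merged) and whose length L is the summed union-exon length in bp, the
#' denominator of the RPKM formula.
#'
#' @param transcripts a `data.frame` with columns `gene_id`, `chrom`,
#'   `strand`, `start0`, `end0` (0-based half-open exon coordinates), one
#'   row per exon over all transcripts; or a named list of `GRanges`
#'   (one element per gene).
#' @return a list with one element per gene: `gene_id`, `chrom`, `strand`,
#'   `exons` (a reduced `GRanges`), `L`.
#' @examples
#' tx <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                  start0 = c(0, 50), end0 = c(100, 150))
#' buildUnionModel(tx)[["g1"]]$L  # 150
#' @export
buildUnionModel <- function(transcripts) {
    if (is.data.frame(transcripts)) {
        split_ <- split(transcripts, transcripts$gene_id)
        models <- lapply(split_, function(df) {
            if (length(unique(df$chrom)) != 1L)
                stop("gene '", df$gene_id[1L],
                     "' has transcripts on different chromosomes")
            ex <- reduce(.gr0(df$chrom, df$start0, df$end0))
            list(gene_id = df$gene_id[1L], chrom = df$chrom[1L],
                 strand = df$strand[1L], exons = ex,
                 L = sum(width(ex)))
        })
    } else {
        models <- lapply(names(transcripts), function(g) {
            gr <- transcripts[[g]]
            if (length(unique(as.character(seqnames(gr)))) != 1L)
                stop("gene '", g, "' has transcripts on different chromosomes")
            ex <- reduce(gr, ignore.strand = TRUE)
            list(gene_id = g, chrom = as.character(seqnames(ex))[1L],
                 strand = as.character(strand(gr))[1L], exons = ex,
                 L = sum(width(ex)))
        })
        names(models) <- names(transcripts)
    }
    models
}

#' Read union gene models from refFlat transcript annotation
#'
#' @param path refFlat file (geneName, name, chrom, strand, txStart, txEnd,
#'   cdsStart, cdsEnd, exonCount, exonStarts, exonEnds).
#' @return union models as from [buildUnionModel()].
#' @export
readUnionModels <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(df)), function(i) {
        s <- as.integer(strsplit(df[i, 10L], ",")[[1L]])
        e <- as.integer(strsplit(df[i, 11L], ",")[[1L]])
        data.frame(gene_id = df[i, 1L], chrom = df[i, 3L],
                   strand = df[i, 4L], start0 = s, end0 = e)
    })
    buildUnionModel(do.call(rbind, rows))
}

#' RPKM from exonic read count, library size and union-exon length
#'
#' `rpkm = n / (N * L) * scale`, with `n` the exonic read count, `N` the
#' total uniquely mapped reads and `L` the union-exon length in bp. The
#' default scale is 1e8, matching the formula as printed in the source
#' methods; pass `scale = 1e9` for the conventional
#' reads-per-kilobase-per-million definition (exactly 10x larger).
#'
#' @param n exonic read count (vectorised).
#' @param N total uniquely mapped reads (> 0).
#' @param L union-exon length in bp (> 0).
#' @param scale scaling constant (default 1e8).
#' @return numeric RPKM values.
#' @examples
#' computeRpkm(10, 1e6, 1e3)  # 1.0
#' @export
computeRpkm <- function(n, N, L, scale = 1e8) {
    if (any(N < 1)) stop("'N' must be >= 1")
    if (any(L < 1)) stop("'L' must be >= 1")
    n / (N * L) * scale
}

#' Count exonic reads per gene
#'
#' A read is counted for a gene when its 5' position lies within a union
#' exon of that gene. Reads whose 5' position falls in exons of several
#' genes are assigned to the single gene with the smaller exon start
#' (deterministic tie-break), so each read counts at most once.
#'
#' @param alignments a width-1 (or wider; the 5' position is `start` for
#'   `+`/unstranded and `end` for `-`) `GRanges` of read positions.
#' @param models union models from [buildUnionModel()].
#' @return named integer vector of exonic read counts per gene.
#' @export
countExonicReads <- function(alignments, models) {
    minus <- as.character(strand(alignments)) == "-"
    p1 <- ifelse(minus, end(alignments), start(alignments))
    pts <- GRanges(seqnames(alignments), IRanges(p1, p1))
    counts <- stats::setNames(integer(length(models)), names(models))
    geneStart <- vapply(models, function(m) min(start(m$exons)), 0L)
    assigned <- rep(NA_integer_, length(pts))
    assignedStart <- rep(Inf, length(pts))
    for (gi in seq_along(models)) {
        hit <- overlapsAny(pts, models[[gi]]$exons)
        take <- hit & geneStart[gi] < assignedStart
        assigned[take] <- gi
        assignedStart[take] <- geneStart[gi]
    }
    tab <- table(factor(assigned, levels = seq_along(models)))
    counts[] <- as.integer(tab)
    counts
}

#' Expression table with RPKM per gene
#'
#' @param alignments read positions as in [countExonicReads()].
#' @param models union models from [buildUnionModel()].
#' @param N total uniquely mapped reads; defaults to `length(alignments)`.
#' @param scale RPKM scaling constant (default 1e8).
#' @return a `data.frame` with columns `gene_id`, `n`, `N`, `L`, `rpkm`.
#' @export
expressionTable <- function(alignments, models, N = length(alignments),
                            scale = 1e8) {
    n <- countExonicReads(alignments, models)
    L <- vapply(models, function(m) m$L, 0)
    data.frame(gene_id = names(models), n = as.integer(n), N = N, L = L,
               rpkm = computeRpkm(n, N, L, scale), row.names = NULL)
}

#' Mann-Whitney (Wilcoxon rank-sum) test between two groups
#'
#' Two-sided test via [stats::wilcox.test()]: exact for small untied
#' samples, normal approximation with tie correction otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @return a list with `U` (the Mann-Whitney U statistic for `x`) and
#'   `p.value`.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitney <- function(x, y) {
    if (!length(x) || !length(y))
        stop("both groups must be non-empty")
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    p <- wt$p.value
    # every pooled value tied: the tie-corrected variance is zero and the
    # approximation is undefined; there is no evidence of a difference
    if (is.na(p)) p <- 1
    list(U = unname(wt$statistic), p.value = p)
}
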