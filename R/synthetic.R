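# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments plus a seed: repeated calls are bit-identical, and each
# generator draws from its own substream of the global seed so adding a
# generator never perturbs existing fixtures. Truth tables are first-class
# return values so recovery of planted structure can be asserted by any
# downstream stage.

#' Generate a synthetic genome with planted CpG islands and motifs
#'
#' Background bases are drawn i.i.d. at the requested GC fraction; island
#' intervals are overwritten with CpG-dense sequence; motif instances are
#' written verbatim at their planted positions (an error is raised if two
#' planted motifs would overlap). The returned truth tables are exact: CpG
#' positions and motif hits are recomputed by scanning the final sequence,
#' so background (unplanted) occurrences are included and flagged.
#'
#' @param length genome length in bp.
#' @param gcFraction background GC fraction in \[0, 1\].
#' @param islands optional `data.frame` with columns `start0`, `width`,
#'   `cpgDensity` (probability of planting a CG at each even offset).
#' @param motifs optional `data.frame` with columns `pattern` (literal
#'   ACGT string) and `pos0`.
#' @param chrom chromosome name (default `"chrS"`).
#' @param seed integer seed (mandatory).
#' @return a list: `genome`, a named `DNAStringSet`; `cpg0`, 0-based
#'   positions of all CG dinucleotides; `islands`, a `GRanges`;
#'   `motifHits`, a `data.frame` of all plus-strand occurrences of each
#'   planted pattern with a logical `planted` column.
#' @export
synthGenome <- function(length, gcFraction = 0.4, islands = NULL,
                        motifs = NULL, chrom = "chrS", seed) {
    stopifnot(length > 0, gcFraction >= 0, gcFraction <= 1)
    .with_seed(.substream_seed(seed, "genome"), {
        p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
               G = gcFraction / 2, T = (1 - gcFraction) / 2)
        bases <- sample(names(p), length, replace = TRUE, prob = p)
        if (!is.null(islands)) {
            for (i in seq_len(nrow(islands))) {
                s0 <- islands$start0[i]; w <- islands$width[i]
                idx <- (s0 + 1L):(s0 + w)
                bases[idx] <- sample(c("A", "C", "G", "T"), w,
                                     replace = TRUE,
                                     prob = c(.15, .35, .35, .15))
                even <- seq(s0, s0 + w - 2L, by = 2L)
                plant <- even[stats::runif(base::length(even)) <
                                  islands$cpgDensity[i]]
                bases[plant + 1L] <- "C"
                bases[plant + 2L] <- "G"
            }
        }
        if (!is.null(motifs)) {
            iv <- .gr0(chrom, motifs$pos0, motifs$pos0 + nchar(motifs$pattern))
            if (!isDisjoint(iv))
                stop("planted motifs overlap")
            for (i in seq_len(nrow(motifs))) {
                chars <- strsplit(motifs$pattern[i], "")[[1L]]
                bases[motifs$pos0[i] + seq_along(chars)] <- chars
            }
        }
        seqstr <- paste(bases, collapse = "")
        genome <- Biostrings::DNAStringSet(stats::setNames(seqstr, chrom))
        cpg0 <- scanIupac(seqstr, "CG", bothStrands = FALSE,
                          chrom = chrom)$start0
        motifHits <- NULL
        if (!is.null(motifs)) {
            motifHits <- do.call(rbind, lapply(unique(motifs$pattern),
                function(pat) {
                    h <- scanIupac(seqstr, pat, chrom = chrom)
                    h$planted <- h$start0 %in%
                        motifs$pos0[motifs$pattern == pat] & h$strand == "+"
                    h
                }))
        }
        list(genome = genome, cpg0 = cpg0,
             islands = if (is.null(islands)) GRanges()
                       else .gr0(chrom, islands$start0,
                                 islands$start0 + islands$width),
             motifHits = motifHits)
    })
}

#' Generate replicate peak sets with planted true sites
#'
#' True binding sites appear in both replicates with independent center
#' jitter and multiplicative height noise; each replicate additionally
#' receives false peaks placed away from every true site. The merged set
#' is the interval union of both replicates with summed heights, emulating
#' a peak call on pooled reads.
#'
#' @param nTrue number of true sites.
#' @param nNoise false peaks per replicate.
#' @param genomeLength genome length in bp.
#' @param peakWidth peak width in bp.
#' @param jitterSd replicate center jitter standard deviation in bp.
#' @param tallFraction fraction of true sites drawn from the tall-height
#'   component (default 0.1: a tall minority over a short majority, the
#'   shape that gives rank curves their inflection).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return a list with [PeakSet]s `rep1`, `rep2`, `merged`; `truth`, a
#'   `GRanges` of the true sites with planted heights; and `noise1`,
#'   `noise2`, the false-peak intervals per replicate.
#' @export
synthPeakReplicates <- function(nTrue = 100L, nNoise = 50L,
                                genomeLength = 1e6, peakWidth = 200L,
                                jitterSd = 10, tallFraction = 0.1,
                                chrom = "chrS", seed) {
    .with_seed(.substream_seed(seed, "peaks"), {
        slots <- seq(peakWidth, genomeLength - peakWidth,
                     by = 4L * peakWidth)
        need <- nTrue + 2L * nNoise
        if (base::length(slots) < need)
            stop("genome too short for the requested site count")
        pick <- sample(slots, need)
        trueC <- pick[seq_len(nTrue)]
        noiseC <- list(pick[nTrue + seq_len(nNoise)],
                       pick[nTrue + nNoise + seq_len(nNoise)])
        tall <- stats::runif(nTrue) < tallFraction
        trueH <- ifelse(tall, round(stats::runif(nTrue, 40, 200)),
                        round(stats::runif(nTrue, 5, 39)))
        hw <- peakWidth %/% 2L
        mkRep <- function(centers, heights, label) {
            c2 <- centers + round(stats::rnorm(base::length(centers),
                                               0, jitterSd))
            h2 <- pmax(1, round(heights *
                exp(stats::rnorm(base::length(centers), 0, 0.15))))
            PeakSet(.gr0(chrom, pmax(c2 - hw, 0L), c2 + hw),
                    height = h2, source = label)
        }
        noiseH <- function(n) round(stats::runif(n, 5, 30))
        rep1 <- mkRep(c(trueC, noiseC[[1L]]),
                      c(trueH, noiseH(nNoise)), "rep1")
        rep2 <- mkRep(c(trueC, noiseC[[2L]]),
                      c(trueH, noiseH(nNoise)), "rep2")
        pooled <- c(as(rep1, "GRanges"), as(rep2, "GRanges"))
        mergedIv <- reduce(pooled, ignore.strand = TRUE)
        ov <- findOverlaps(pooled, mergedIv)
        hSum <- tapply(mcols(pooled)$height[queryHits(ov)],
                       subjectHits(ov), sum)
        merged <- PeakSet(mergedIv, height = as.numeric(hSum),
                          source = "merged")
        truth <- .gr0(chrom, trueC - hw, trueC + hw)
        mcols(truth)$height <- trueH
        list(rep1 = rep1, rep2 = rep2, merged = merged, truth = truth,
             noise1 = .gr0(chrom, noiseC[[1L]] - hw, noiseC[[1L]] + hw),
             noise2 = .gr0(chrom, noiseC[[2L]] - hw, noiseC[[2L]] + hw))
    })
}

#' Generate bisulfite calls over known CpG positions
#'
#' Per CpG, total reads are Poisson at the mean depth (zero-coverage CpGs
#' are dropped; RRBS-like sparsity is emulated by first keeping each site
#' with probability `siteProb`) and methylated reads are binomial at the
#' planted regional beta.
#'
#' @param cpg0 0-based CpG cytosine positions.
#' @param levels a `GRanges` with a `beta` metadata column (percent)
#'   defining regional methylation; CpGs outside every region get
#'   `backgroundBeta`.
#' @param meanDepth mean sequencing depth.
#' @param siteProb probability a site is assayed at all (1 = WGBS-like
#'   dense coverage; ~0.1 = RRBS-like sparse coverage).
#' @param backgroundBeta percent methylation outside planted regions.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return a list with `calls` (a CpG call `GRanges`, see [cpgCalls()]) and
#'   `truth`, a `data.frame` of each emitted CpG's planted beta.
#' @export
synthBisulfite <- function(cpg0, levels = NULL, meanDepth = 20,
                           siteProb = 1, backgroundBeta = 70,
                           chrom = "chrS", seed) {
    .with_seed(.substream_seed(seed, "bisulfite"), {
        keep <- stats::runif(base::length(cpg0)) < siteProb
        pos0 <- cpg0[keep]
        beta <- rep(backgroundBeta, base::length(pos0))
        if (!is.null(levels) && base::length(levels)) {
            pts <- .gr0(chrom, pos0, pos0 + 1L)
            ov <- findOverlaps(pts, levels, select = "first")
            hit <- !is.na(ov)
            beta[hit] <- mcols(levels)$beta[ov[hit]]
        }
        total <- stats::rpois(base::length(pos0), meanDepth)
        cov <- total > 0L
        pos0 <- pos0[cov]; beta <- beta[cov]; total <- total[cov]
        meth <- stats::rbinom(base::length(pos0), total, beta / 100)
        list(calls = cpgCalls(rep(chrom, base::length(pos0)), pos0, meth,
                              total),
             truth = data.frame(pos0 = pos0, beta = beta, total = total))
    })
}

#' Generate ChIP-like tag alignments with Gaussian piles at anchors
#'
#' Background tags are uniform over the genome at `backgroundRate` tags
#' per bp. Each anchor receives a Gaussian pile of fragment centers
#' (standard deviation `pileSd`) whose expected count makes the central
#' density `fold` times the background; 5' tag positions flank the anchor
#' (`+` tags upstream, `-` tags downstream, each offset by half a fragment)
#' to mimic ChIP fragment structure.
#'
#' @param anchors0 0-based anchor center positions.
#' @param fold central enrichment over background (>= 1; 1 means no pile).
#' @param pileSd Gaussian pile standard deviation in bp.
#' @param backgroundRate background tags per bp.
#' @param genomeLength genome length in bp.
#' @param fragment fragment length in bp (default 150).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return a width-1 stranded `GRanges` of 5' tag positions.
#' @export
synthTags <- function(anchors0, fold = 10, pileSd = 100,
                      backgroundRate = 0.01, genomeLength = 1e6,
                      fragment = 150L, chrom = "chrS", seed) {
    if (fold < 1) stop("'fold' must be >= 1")
    .with_seed(.substream_seed(seed, "tags"), {
        nBg <- stats::rpois(1L, backgroundRate * genomeLength)
        centers <- stats::runif(nBg, 0, genomeLength)
        if (fold > 1 && base::length(anchors0)) {
            perAnchor <- (fold - 1) * backgroundRate * pileSd * sqrt(2 * pi)
            nPile <- stats::rpois(base::length(anchors0), perAnchor)
            pile <- rep(anchors0, nPile) +
                stats::rnorm(sum(nPile), 0, pileSd)
            centers <- c(centers, pile)
        }
        strand <- ifelse(stats::runif(base::length(centers)) < 0.5,
                         "+", "-")
        p0 <- round(ifelse(strand == "+", centers - fragment / 2,
                           centers + fragment / 2))
        ok <- p0 >= 0 & p0 < genomeLength
        .gr0(chrom, as.integer(p0[ok]), as.integer(p0[ok]) + 1L,
             strand = strand[ok])
    })
}

#' Generate RNA-seq-like alignments from planted expression levels
#'
#' Per-gene exonic read counts are Poisson with mean
#' `rpkm * N * L / scale`, so the RPKM estimate recovered from the reads
#' is unbiased for the planted level; reads are placed uniformly within
#' union exons on the gene's strand.
#'
#' @param models union models from [buildUnionModel()].
#' @param rpkm named numeric vector of planted RPKM per gene.
#' @param N total uniquely mapped reads in the emulated experiment (the
#'   RPKM denominator).
#' @param scale RPKM scale constant (default 1e8).
#' @param seed integer seed.
#' @return a list with `alignments` (width-1 `GRanges` of 5' read
#'   positions) and `truth`, a `data.frame` of gene, planted rpkm and
#'   drawn count.
#' @export
synthExpression <- function(models, rpkm, N, scale = 1e8, seed) {
    stopifnot(all(rpkm >= 0), all(names(models) %in% names(rpkm)))
    .with_seed(.substream_seed(seed, "expression"), {
        chroms <- character(0); pos <- integer(0)
        truth <- data.frame(gene_id = names(models),
                            rpkm = unname(rpkm[names(models)]), n = 0L)
        for (gi in seq_along(models)) {
            m <- models[[gi]]
            mu <- rpkm[[m$gene_id]] * N * m$L / scale
            n <- stats::rpois(1L, mu)
            truth$n[gi] <- n
            if (n == 0L) next
            offs <- sample.int(m$L, n, replace = TRUE)
            cum <- cumsum(width(m$exons))
            exi <- findInterval(offs - 1L, c(0L, cum),
                                rightmost.closed = FALSE)
            within <- offs - c(0L, cum)[exi] - 1L
            pos <- c(pos, start(m$exons)[exi] + within)
            chroms <- c(chroms, rep(m$chrom, n))
        }
        list(alignments = GRanges(chroms, IRanges(pos, pos),
                                  strand = rep("+", base::length(pos))),
             truth = truth)
    })
}
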