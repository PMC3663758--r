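# End-to-end orchestration on synthetic two-cell data: emulates the full
# study design (replicate ChIP peaks, bisulfite calls, nucleosome tags and
# expression for two cell types with planted cell-type-specific structure)
# and runs every analysis stage over it.

#' Generate a complete synthetic two-cell-type study
#'
#' Plants the structure the integrative analysis is designed to detect:
#' binding sites shared by both cell types sit at unmethylated,
#' nucleosome-free, highly expressed promoters in both cells; sites unique
#' to one cell type are methylated and nucleosome-occupied in the *other*
#' cell, and their target genes are expressed mainly in the bound cell.
#' Every site carries a central CGCG; a subset of common sites additionally
#' carries the full TCTCGCGAGA recognition motif while most cell-unique
#' sites lack it.
#'
#' @param nCommon,nUniqueA,nUniqueB site counts per class.
#' @param genomeLength genome length in bp.
#' @param siteWidth binding-site width in bp.
#' @param motifFracCommon,motifFracUnique fraction of common /
#'   cell-unique sites carrying the full 10-bp motif.
#' @param lowBeta,highBeta planted percent methylation at accessible /
#'   silenced sites.
#' @param meanDepth bisulfite mean sequencing depth.
#' @param nReads emulated RNA-seq library size (RPKM denominator).
#' @param seed integer seed (mandatory; all generator substreams derive
#'   from it).
#' @return a list bundling the genome, per-cell replicate [PeakSet]s,
#'   bisulfite calls, MNase-like tag sets, gene models, expression
#'   alignments and all truth tables.
#' @export
synthTwoCellStudy <- function(nCommon = 60L, nUniqueA = 40L, nUniqueB = 40L,
                              genomeLength = 6e5, siteWidth = 200L,
                              motifFracCommon = 0.6, motifFracUnique = 0.15,
                              lowBeta = 5, highBeta = 80,
                              meanDepth = 20, nReads = 1e6, seed) {
    chrom <- "chrS"
    nSites <- nCommon + nUniqueA + nUniqueB
    spacing <- as.integer(genomeLength %/% (nSites + 1L))
    if (spacing < siteWidth + 2200L)
        stop("genome too short for the requested site count")
    centers <- spacing * seq_len(nSites)
    class <- rep(c("common", "unique_a", "unique_b"),
                 c(nCommon, nUniqueA, nUniqueB))
    motif <- "TCTCGCGAGA"
    hasMotif <- .with_seed(.substream_seed(seed, "study"), {
        ifelse(class == "common",
               stats::runif(nSites) < motifFracCommon,
               stats::runif(nSites) < motifFracUnique)
    })
    # full motif carries its CGCG core; other sites get a bare CGCG
    plant <- data.frame(
        pattern = ifelse(hasMotif, motif, "CGCG"),
        pos0 = ifelse(hasMotif, centers - 5L, centers - 2L))
    gen <- synthGenome(genomeLength, gcFraction = 0.45, motifs = plant,
                       chrom = chrom, seed = seed)
    hw <- siteWidth %/% 2L
    sites <- .gr0(chrom, centers - hw, centers + hw)
    mcols(sites)$class <- class
    mcols(sites)$has_motif <- hasMotif
    mcols(sites)$gene_id <- sprintf("gene%03d", seq_len(nSites))

    # replicate peak sets per cell: common sites are the tall class
    mkCell <- function(cellClass, cellSeed) {
        idx <- which(class %in% cellClass)
        h <- ifelse(class[idx] == "common",
                    round(stats::runif(base::length(idx), 40, 120)),
                    round(stats::runif(base::length(idx), 12, 40)))
        reps <- lapply(1:2, function(r) {
            c2 <- centers[idx] + round(stats::rnorm(base::length(idx), 0, 8))
            h2 <- pmax(1, round(h * exp(stats::rnorm(base::length(idx),
                                                     0, 0.15))))
            # per-replicate false peaks in the gaps between sites; the
            # offset differs by replicate so noise is never reproducible
            nNoise <- max(5L, base::length(idx) %/% 5L)
            gaps <- centers[-idx] + r * (spacing %/% 3L)
            noiseC <- sample(gaps, min(nNoise, base::length(gaps)))
            PeakSet(.gr0(chrom, c(c2, noiseC) - hw, c(c2, noiseC) + hw),
                    height = c(h2, round(stats::runif(
                        base::length(noiseC), 5, 25))),
                    source = paste0("rep", r))
        })
        list(rep1 = reps[[1L]], rep2 = reps[[2L]], siteIdx = idx)
    }
    cellA <- .with_seed(.substream_seed(seed * 7 + 1, "study"),
                        mkCell(c("common", "unique_a"), seed))
    cellB <- .with_seed(.substream_seed(seed * 7 + 2, "study"),
                        mkCell(c("common", "unique_b"), seed))

    # methylation truth: a site is unmethylated in the cell that binds it,
    # highly methylated in the other cell; background between sites high
    mkLevels <- function(openClass) {
        lv <- sites
        mcols(lv)$beta <- ifelse(class %in% openClass, lowBeta, highBeta)
        lv[, "beta"]
    }
    bisA <- synthBisulfite(gen$cpg0, mkLevels(c("common", "unique_a")),
                           meanDepth = meanDepth, backgroundBeta = 70,
                           chrom = chrom, seed = seed * 11 + 1)
    bisB <- synthBisulfite(gen$cpg0, mkLevels(c("common", "unique_b")),
                           meanDepth = meanDepth, backgroundBeta = 70,
                           chrom = chrom, seed = seed * 11 + 2)

    # nucleosome occupancy: piles at sites NOT bound in that cell
    mnaseA <- synthTags(centers[class == "unique_b"], fold = 8,
                        pileSd = 80, backgroundRate = 0.02,
                        genomeLength = genomeLength, fragment = 147L,
                        chrom = chrom, seed = seed * 13 + 1)
    mnaseB <- synthTags(centers[class == "unique_a"], fold = 8,
                        pileSd = 80, backgroundRate = 0.02,
                        genomeLength = genomeLength, fragment = 147L,
                        chrom = chrom, seed = seed * 13 + 2)

    # one gene per site: TSS at the site center, two exons downstream
    tx <- data.frame(gene_id = mcols(sites)$gene_id, chrom = chrom,
                     strand = "+",
                     start0 = centers, end0 = centers + 700L)
    tx2 <- transform(tx, start0 = centers + 900L, end0 = centers + 1700L)
    models <- buildUnionModel(rbind(tx, tx2))
    tss <- .gr0(chrom, centers, centers + 1L, strand = "+")
    mcols(tss)$gene_id <- mcols(sites)$gene_id

    rpkmTruth <- function(onClass) {
        stats::setNames(ifelse(class == "common", 10,
                               ifelse(class %in% onClass, 5, 0.5)),
                        mcols(sites)$gene_id)
    }
    exprA <- synthExpression(models, rpkmTruth("unique_a"), N = nReads,
                             seed = seed * 17 + 1)
    exprB <- synthExpression(models, rpkmTruth("unique_b"), N = nReads,
                             seed = seed * 17 + 2)

    list(chrom = chrom, genome = gen$genome, cpg0 = gen$cpg0,
         motif = motif, sites = sites, centers = centers,
         cellA = cellA, cellB = cellB,
         bisA = bisA, bisB = bisB,
         mnaseA = mnaseA, mnaseB = mnaseB,
         models = models, tss = tss, nReads = nReads,
         exprA = exprA, exprB = exprB,
         lowBeta = lowBeta, highBeta = highBeta, seed = seed)
}

#' Run the full integrative pipeline on a synthetic two-cell study
#'
#' Executes every stage in order — replicate reproducibility,
#' high-confidence peak derivation, cross-cell overlap, promoter
#' proximity, motif annotation, per-CGCG methylation and classification,
#' cross-cell methylation, nucleosome tag density at cell-unique sites,
#' and expression by binding class — and returns a machine-readable
#' summary. With `outDir` set, stage outputs (BED/TSV) and the summary
#' JSON are also written to disk.
#'
#' @param study a bundle from [synthTwoCellStudy()], or NULL to generate
#'   one from `seed`.
#' @param seed integer seed used when `study` is NULL.
#' @param outDir optional output directory.
#' @return a list of stage results plus `summary`, a flat named numeric
#'   vector of headline quantities.
#' @export
runTwoCellPipeline <- function(study = NULL, seed = 1L, outDir = NULL) {
    if (is.null(study))
        study <- synthTwoCellStudy(seed = seed)
    cls <- mcols(study$sites)$class

    repro <- list(A = assessReproducibility(study$cellA$rep1,
                                            study$cellA$rep2),
                  B = assessReproducibility(study$cellB$rep1,
                                            study$cellB$rep2))
    hcA <- deriveHighConfidence(study$cellA$rep1, study$cellA$rep2)
    hcB <- deriveHighConfidence(study$cellB$rep1, study$cellB$rep2)
    truthA <- study$sites[cls %in% c("common", "unique_a")]
    recallA <- 100 * mean(overlapsAny(truthA, hcA))

    comp <- compareCellTypes(hcA, hcB, tss = study$tss)

    partA <- partitionByMotif(hcA, study$genome, study$motif)

    # per-CGCG methylation of cell-unique sites, measured in both cells
    cgcgIn <- function(peaks) {
        ann <- annotateMotifPresence(peaks, study$genome, c(CGCG = "CGCG"))
        ann$hits
    }
    hitsUa <- cgcgIn(comp$unique_a)
    hitsUb <- cgcgIn(comp$unique_b)
    methUa_inA <- motifMethylation(hitsUa, filterCoverage(study$bisA$calls))
    methUa_inB <- motifMethylation(hitsUa, filterCoverage(study$bisB$calls))
    methUb_inA <- motifMethylation(hitsUb, filterCoverage(study$bisA$calls))
    methUb_inB <- motifMethylation(hitsUb, filterCoverage(study$bisB$calls))
    crossMeth <- list(unique_a_in_A = crossCellMethylation(methUa_inA),
                      unique_a_in_B = crossCellMethylation(methUa_inB),
                      unique_b_in_A = crossCellMethylation(methUb_inA),
                      unique_b_in_B = crossCellMethylation(methUb_inB))

    # nucleosome density over B-unique sites in each cell
    ubSites <- study$sites[cls == "unique_b"]
    nucInA <- tagDensity(ubSites, study$mnaseA, halfwidth = 1000L,
                         binSize = 25L, fragment = 147L)
    nucInB <- tagDensity(ubSites, study$mnaseB, halfwidth = 1000L,
                         binSize = 25L, fragment = 147L)
    central <- function(p) {
        v <- profileValues(p)
        mean(v[base::length(v) %/% 2L + c(0L, 1L)], na.rm = TRUE)
    }

    # expression by binding class via nearest-TSS gene assignment
    groupGenes <- function(peaks) {
        if (!base::length(peaks)) return(character(0))
        ann <- classifyLocation(peaks, study$tss)$annotation
        unique(ann$gene_id[ann$proximal & !is.na(ann$gene_id)])
    }
    groups <- list(common = groupGenes(comp$common),
                   unique_a = groupGenes(comp$unique_a),
                   unique_b = groupGenes(comp$unique_b))
    rpkmA <- expressionTable(study$exprA$alignments, study$models,
                             N = study$nReads)
    rpkmB <- expressionTable(study$exprB$alignments, study$models,
                             N = study$nReads)
    exprCmp <- expressionByBindingClass(groups, rpkmA, rpkmB)

    med <- function(grp, cell) {
        s <- exprCmp$summary
        s$median[s$group == grp & s$cell == cell]
    }
    pval <- function(g1, g2, cell) {
        t <- exprCmp$tests
        t$p.value[t$cell == cell & t$group1 == g1 & t$group2 == g2]
    }
    summary <- c(
        repro_pct_forward_a = repro$A@pct_forward,
        repro_pct_reciprocal_a = repro$A@pct_reciprocal,
        repro_passes_a = as.numeric(repro$A@passes_encode),
        hc_peaks_a = base::length(hcA),
        hc_peaks_b = base::length(hcB),
        hc_recall_pct_a = recallA,
        common_peaks = base::length(comp$common),
        unique_peaks_a = base::length(comp$unique_a),
        unique_peaks_b = base::length(comp$unique_b),
        motif_fraction_hc_a = partA$fraction,
        median_meth_unique_b_in_a =
            unname(crossMeth$unique_b_in_A$stats["median"]),
        median_meth_unique_b_in_b =
            unname(crossMeth$unique_b_in_B$stats["median"]),
        nuc_density_center_ratio = central(nucInA) / central(nucInB),
        median_rpkm_common_a = med("common", "A"),
        median_rpkm_unique_b_in_a = med("unique_b", "A"),
        mw_p_common_vs_unique_b_a = pval("common", "unique_b", "A"))

    out <- list(study = study, reproducibility = repro, hcA = hcA,
                hcB = hcB, comparison = comp, motifPartitionA = partA,
                crossMethylation = crossMeth,
                motifMethylation = list(unique_a_in_A = methUa_inA,
                                        unique_a_in_B = methUa_inB,
                                        unique_b_in_A = methUb_inA,
                                        unique_b_in_B = methUb_inB),
                nucleosome = list(unique_b_in_A = nucInA,
                                  unique_b_in_B = nucInB),
                expression = exprCmp, rpkmA = rpkmA, rpkmB = rpkmB,
                groups = groups, summary = summary)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writePeaks(hcA, file.path(outDir, "hc_cellA.bed"))
        writePeaks(hcB, file.path(outDir, "hc_cellB.bed"))
        utils::write.table(exprCmp$summary,
                           file.path(outDir, "expression_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(as.list(summary),
                             file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    out
}
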