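test_that("IUPAC scanning matches degenerate codes and reports overlapping hits", {
    h <- scanIupac("TCCTGCAATT", "TCCTGCNA")
    expect_equal(nrow(h), 1L)
    expect_equal(c(h$start0, h$end0), c(0L, 8L))
    expect_equal(h$matched, "TCCTGCAA")
    h2 <- scanIupac("CGCGCG", "CGCG")
    expect_equal(h2$start0, c(0L, 2L))
    # exhaustive position check for the overlap example
    expect_equal(h2$start0,
                 which(vapply(1:3, function(i)
                     substr("CGCGCG", i, i + 3) == "CGCG", TRUE)) - 1L)
    expect_error(scanIupac("ACGT", "ACX"), "invalid IUPAC")
})

test_that("a palindromic motif collapses to a single plus-strand hit", {
    h <- scanIupac("TCTCGCGAGA", "TCTCGCGAGA", bothStrands = TRUE)
    expect_equal(nrow(h), 1L)
    expect_equal(h$strand, "+")
    # a non-palindromic motif is found on the minus strand in plus coords
    h2 <- scanIupac(revcompStr("TGACCA"), "TGACCA")
    expect_equal(h2$strand, "-")
    expect_equal(c(h2$start0, h2$end0), c(0L, 6L))
})

test_that("N in the subject matches nothing; N in the motif matches ACGT only", {
    expect_equal(nrow(scanIupac("TCCTGCNA", "TCCTGCNA")), 0L)
    expect_equal(nrow(scanIupac("AANAA", "ANA")), 0L)
    expect_equal(nrow(scanIupac("ACGTA", "ANG", bothStrands = FALSE)), 1L)
})

test_that("scanning is strand-symmetric and bounded on random sequences", {
    set.seed(21)
    for (i in 1:25) {
        seq <- randomDna(300)
        # non-palindromic patterns: palindromes collapse their minus hits
        pat <- c("ACGG", "TCCTGCNA", "GATAA", "RYSW")[(i %% 4) + 1]
        fwd <- scanIupac(seq, pat)
        k <- nchar(pat)
        expect_lte(sum(fwd$strand == "+"), 300 - k + 1)
        # + hits on seq equal - hits on revcomp(seq), mapped back
        rc <- scanIupac(revcompStr(seq), pat)
        mapped <- sort(300 - rc$end0[rc$strand == "-"])
        expect_equal(sort(fwd$start0[fwd$strand == "+"]), mapped)
    }
})

test_that("scanner agrees with Biostrings matchPattern on N-free sequences", {
    set.seed(22)
    for (pat in c("CGCG", "TCTCGCGAGA", "TCCTGCNA")) {
        seq <- randomDna(2000)
        mine <- scanIupac(seq, pat, bothStrands = FALSE)
        ref <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                        fixed = FALSE)
        expect_equal(mine$start0, start(ref) - 1L)
    }
})

test_that("motif presence over peaks recovers a planted fraction exactly", {
    set.seed(23)
    n <- 100
    spacing <- 500
    bases <- strsplit(randomDna(n * spacing + 200), "")[[1]]
    starts0 <- (seq_len(n) - 1L) * spacing
    motif <- "TCTCGCGAGA"
    planted <- sample(n, 43)
    for (i in planted)
        bases[starts0[i] + 50 + 1:10] <- strsplit(motif, "")[[1]]
    # scrub accidental background occurrences of the motif core
    genomeStr <- paste(bases, collapse = "")
    peaks <- peaks0("chrT", starts0, starts0 + 200, rep(10, n))
    genome <- toyGenome(chrT = genomeStr)
    ann <- annotateMotifPresence(peaks, genome, c(kaiso = motif))
    expect_gte(ann$fraction[["kaiso"]], 0.43)  # planted at least
    expect_true(all(ann$presence[planted, "kaiso"]))
    # fraction invariant under peak order permutation
    perm <- sample(n)
    annP <- annotateMotifPresence(peaks[perm], genome, c(kaiso = motif))
    expect_equal(annP$fraction, ann$fraction)
    # absent motif gives fraction 0
    expect_equal(
        annotateMotifPresence(peaks, genome,
                              c(none = "TTTTTTTTTTTTAAAAAAAAAAAA"))$fraction,
        c(none = 0))
    # a motif equal to one whole peak sequence flags that peak
    pk1seq <- substr(genomeStr, starts0[2] + 1, starts0[2] + 200)
    one <- annotateMotifPresence(peaks, genome, c(self = pk1seq))
    expect_true(one$presence[2, "self"])
    expect_error(annotateMotifPresence(peaks0("chrZ", 0, 10, 1), genome, "CG"),
                 "chrZ")
})

test_that("recentering picks the hit nearest the peak midpoint, leftmost on ties", {
    pk <- peaks0("chr1", 1000, 1200, 10)
    hits <- data.frame(chrom = "chr1", start0 = 1100L, end0 = 1110L,
                       strand = "+", motif = "m", matched = "", peak = 1L)
    rc <- recenterOnMotif(pk, hits, halfwidth = 250)
    expect_equal(mcols(rc)$anchor0, 1105L)
    expect_equal(c(start(rc) - 1L, end(rc)), c(1105L - 250L, 1105L + 250L))
    # two hits equidistant from midpoint 1100: leftmost wins
    hits2 <- data.frame(chrom = "chr1", start0 = c(1060L, 1130L),
                        end0 = c(1070L, 1140L), strand = "+", motif = "m",
                        matched = "", peak = 1L)
    expect_equal(mcols(recenterOnMotif(pk, hits2, 100))$anchor0, 1065L)
    # peaks without hits are dropped
    pks <- c(as(pk, "GRanges"), GRanges("chr1", IRanges(5001, 5200)))
    mcols(pks)$height <- c(10, 10)
    rc2 <- recenterOnMotif(PeakSet(pks), hits, 100)
    expect_length(rc2, 1L)
    expect_error(recenterOnMotif(pk, hits, 0), "halfwidth")
})

test_that("recentered anchors equal planted motif positions on synthetic peaks", {
    set.seed(25)
    centers <- seq(1000, 20000, by = 1000)
    offs <- sample(-80:80, length(centers), TRUE)
    hitStarts <- centers + offs
    hits <- data.frame(chrom = "chrS", start0 = hitStarts,
                       end0 = hitStarts + 10L, strand = "+", motif = "m",
                       matched = "", peak = seq_along(centers))
    pk <- peaks0("chrS", centers - 100, centers + 100,
                 rep(5, length(centers)))
    rc <- recenterOnMotif(pk, hits, 250)
    expect_equal(mcols(rc)$anchor0, hitStarts + 5L)
})

test_that("hypergeometric enrichment matches closed forms", {
    e <- motifEnrichmentTest(10, 10, 0, 10)
    expect_equal(e$p.value, 1 / choose(20, 10))
    expect_identical(e$ratio, Inf)
    flat <- motifEnrichmentTest(5, 10, 5, 10)
    expect_equal(flat$ratio, 1)
    expect_gt(flat$p.value, 0.5)
    none <- motifEnrichmentTest(0, 10, 5, 10)
    expect_equal(none$ratio, 0)
    expect_equal(none$p.value, 1)
    # oracle: exact tail sum of the hypergeometric pmf
    ptail <- sum(dhyper(6:10, 9, 11, 10))
    expect_equal(motifEnrichmentTest(6, 10, 3, 10)$p.value, ptail)
})
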