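test_that("readPeaks assigns ranks by descending score with positional tie-break", {
    f <- writeBedLines(c("chr1\t100\t200\t50",
                         "chr1\t300\t400\t90",
                         "chr2\t0\t10\t90"))
    p <- readPeaks(f)
    expect_s4_class(p, "PeakSet")
    expect_length(p, 3L)
    # chr1:300 and chr2:0 tie at 90; chr1 sorts before chr2
    expect_equal(peakRanks(p), c(3L, 1L, 2L))
    expect_equal(rankCurve(p)$height, c(90, 90, 50))
})

test_that("readPeaks handles empty files and reports malformed lines", {
    expect_length(readPeaks(writeBedLines(character(0))), 0L)
    expect_error(readPeaks(writeBedLines("chr1\t200\t100")),
                 "line 1.*end must exceed start")
    expect_error(readPeaks(writeBedLines(c("chr1\t0\t10\t5", "chr1\tx\ty"))),
                 "line 2")
})

test_that("overlap uses shared base pairs: 1 bp counts, abutting does not", {
    a <- peaks0("chr1", 100, 200, 10)
    withBp <- overlapPeakSets(a, peaks0("chr1", 199, 300, 10))
    expect_length(commonPeaks(withBp)$a, 1L)
    abutting <- overlapPeakSets(a, peaks0("chr1", 200, 300, 10))
    expect_length(commonPeaks(abutting)$a, 0L)
    expect_error(overlapPeakSets(a, a, minOverlap = 0), "minOverlap")
})

test_that("overlap counts are conserved and symmetric under argument swap", {
    set.seed(42)
    for (i in 1:20) {
        s1 <- sort(sample(0:5000, 10)) * 2
        s2 <- sort(sample(0:5000, 8)) * 2
        a <- peaks0("chr1", s1, s1 + sample(50:150, 10, TRUE),
                    sample(1:99, 10))
        b <- peaks0("chr1", s2, s2 + sample(50:150, 8, TRUE),
                    sample(1:99, 8))
        ov <- overlapPeakSets(a, b)
        expect_equal(length(commonPeaks(ov)$a) + length(uniquePeaks(ov)$a),
                     length(a))
        expect_equal(length(commonPeaks(ov)$b) + length(uniquePeaks(ov)$b),
                     length(b))
        rev <- overlapPeakSets(b, a)
        expect_equal(granges(as(commonPeaks(ov)$a, "GRanges")),
                     granges(as(commonPeaks(rev)$b, "GRanges")))
    }
})

test_that("shifted-within-width peaks are mutually common", {
    s <- seq(0, 9000, by = 1000)
    a <- peaks0("chr1", s, s + 200, rep(10, 10))
    b <- peaks0("chr1", s + 5, s + 205, rep(10, 10))
    ov <- overlapPeakSets(a, b)
    # brute-force pairwise check of the same question
    brute <- outer(seq_along(s), seq_along(s), function(i, j)
        pmin(s[i] + 200, s[j] + 205) - pmax(s[i], s[j] + 5) > 0)
    expect_equal(length(commonPeaks(ov)$a), sum(rowSums(brute) > 0))
    expect_length(commonPeaks(ov)$a, 10L)
    expect_length(commonPeaks(ov)$b, 10L)
})

test_that("high-confidence derivation recovers planted truth and honors coordinate source", {
    s <- synthPeakReplicates(nTrue = 100, nNoise = 50, seed = 7)
    hc <- deriveHighConfidence(s$rep1, s$rep2)
    # every true site recovered; coincidental noise overlaps are possible
    # but noise is planted disjoint so recall is exact
    expect_equal(sum(overlapsAny(s$truth, hc)), 100L)
    expect_true(all(overlapsAny(hc, s$rep1)))
    # identity: rep1 == rep2 returns rep1
    same <- deriveHighConfidence(s$rep1, s$rep1)
    expect_length(same, length(s$rep1))
    # disjoint chromosomes give the empty set
    other <- peaks0("chrZ", 0, 100, 5)
    expect_length(deriveHighConfidence(s$rep1, other), 0L)
    # merged mode: output is a subset of merged coordinates
    hcM <- deriveHighConfidence(s$rep1, s$rep2, merged = s$merged)
    expect_true(all(overlapsAny(hcM, s$merged, type = "equal")))
    expect_identical(metadata(hcM)$hc_mode, "merged")
})

test_that("reproducibility matches the hand-enumerated 40%-rule example", {
    s <- seq(0, 9000, by = 1000)
    rep1 <- peaks0("chr1", s, s + 200, height = 10:1)
    rep2 <- selectTopFraction(rep1, 0.5)  # top 5 of rep1
    r <- assessReproducibility(rep1, rep2)
    expect_equal(r@pct_forward, 100)
    expect_equal(r@pct_reciprocal, 100)
    expect_equal(r@count_ratio, 2)
    expect_true(r@passes_encode)
})

test_that("reproducibility of a set with itself is 100/100/pass; disjoint sets fail", {
    set.seed(11)
    s <- sort(sample(seq(0, 5e4, by = 500), 30))
    p <- peaks0("chr1", s, s + 100, sample(1:50, 30, TRUE))
    r <- assessReproducibility(p, p)
    expect_equal(c(r@pct_forward, r@pct_reciprocal), c(100, 100))
    expect_equal(r@count_ratio, 1)
    expect_true(r@passes_encode)
    moved <- peaks0("chr2", s, s + 100, sample(1:50, 30, TRUE))
    r2 <- assessReproducibility(p, moved)
    expect_equal(c(r2@pct_forward, r2@pct_reciprocal), c(0, 0))
    expect_false(r2@passes_encode)
    expect_error(assessReproducibility(p, peaks0("chr1", 1, 2, 1)[0]),
                 "non-empty")
})

test_that("selectTopFraction keeps the ceiling of fraction * n tallest peaks", {
    p <- peaks0("chr1", seq(0, 6000, by = 1000), seq(0, 6000, by = 1000) + 100,
                height = c(70, 10, 50, 30, 20, 60, 40))
    expect_length(selectTopFraction(p, 0.4), 3L)  # ceiling(2.8)
    expect_equal(sort(peakHeights(selectTopFraction(p, 0.4))), c(50, 60, 70))
    expect_length(selectTopFraction(p, 1), 7L)
    expect_error(selectTopFraction(p, 0), "fraction")
    expect_error(selectTopFraction(p, 1.2), "fraction")
})

test_that("location classification agrees with a brute-force nearest-TSS oracle", {
    set.seed(3)
    for (rep in 1:5) {
        n <- 20
        pstart <- sample(0:20000, n)
        peaks <- peaks0("chr1", pstart, pstart + sample(100:400, n, TRUE),
                        sample(1:99, n))
        tpos <- sample(0:20000, 8)
        tstrand <- sample(c("+", "-"), 8, TRUE)
        tss <- tss0("chr1", tpos, tstrand)
        cl <- classifyLocation(peaks, tss, window = 1000)
        mid0 <- (pstart + (pstart + width(peaks))) %/% 2
        for (i in seq_len(n)) {
            d <- mid0[i] - tpos
            expect_equal(cl$annotation$proximal[i], any(abs(d) <= 1000))
            j <- which.min(abs(d))
            expect_equal(cl$annotation$gene_id[i], sprintf("g%d", j))
            expect_equal(cl$annotation$distance[i],
                         if (tstrand[j] == "-") -d[j] else d[j])
        }
        expect_equal(length(cl$proximal) + length(cl$distal), n)
    }
})

test_that("location boundary at exactly the window size is proximal", {
    p <- peaks0("chr1", 1950, 2050, 10)      # midpoint 2000
    expect_length(classifyLocation(p, tss0("chr1", 1000), 1000)$proximal, 1L)
    expect_length(classifyLocation(p, tss0("chr1", 999), 1000)$proximal, 0L)
    # peak on a chromosome without any TSS is distal
    p2 <- peaks0("chr9", 0, 100, 1)
    expect_length(classifyLocation(p2, tss0("chr1", 0), 1000)$distal, 1L)
    expect_warning(cl <- classifyLocation(p, tss0("chr1", 1)[0]), "empty TSS")
    expect_length(cl$distal, 1L)
})

test_that("blacklist filtering removes overlapping peaks, conserves counts and is idempotent", {
    set.seed(5)
    s <- seq(0, 99000, by = 1000)[1:100]
    p <- peaks0("chr1", s, s + 200, sample(1:99, 100, TRUE))
    bl <- GRanges("chr1", IRanges(s[1:30] + 1, s[1:30] + 200))
    kept <- filterBlacklist(p, bl)
    expect_length(kept, 70L)
    expect_length(metadata(kept)$removed, 30L)
    expect_length(filterBlacklist(kept, bl), 70L)   # idempotent
    expect_length(filterBlacklist(p, GRanges()), 100L)
    wholeChrom <- GRanges("chr1", IRanges(1, 1e6))
    expect_length(filterBlacklist(p, wholeChrom), 0L)
})

test_that("rank curves are non-increasing, including on mixture heights", {
    expect_equal(nrow(rankCurve(peaks0("chr1", 1, 2, 1)[0])), 0L)
    set.seed(8)
    n <- 1000
    h <- ifelse(runif(n) < 0.1, runif(n, 40, 200), runif(n, 1, 39))
    s <- seq_len(n) * 300
    rc <- rankCurve(peaks0("chr1", s, s + 200, round(h)))
    expect_false(is.unsorted(rev(rc$height)))
    expect_equal(rc$rank, seq_len(n))
    expect_equal(sort(rc$height), sort(round(h)))
})
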