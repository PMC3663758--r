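test_that("merging call sets sums counts at shared positions and concatenates elsewhere", {
    a <- cpgCalls("chr1", c(100, 200), meth = c(5, 1), total = c(10, 2))
    b <- cpgCalls("chr1", c(100, 300), meth = c(3, 2), total = c(10, 4))
    m <- mergeCallSets(a, b)
    expect_length(m, 3L)
    at100 <- m[start(m) == 101]
    expect_equal(mcols(at100)$meth_reads, 8L)
    expect_equal(mcols(at100)$total_reads, 20L)
    expect_equal(mcols(at100)$beta, 40)
    # disjoint positions concatenate
    d <- mergeCallSets(cpgCalls("chr1", 1, 1, 2), cpgCalls("chr2", 1, 0, 2))
    expect_length(d, 2L)
})

test_that("merging a set with itself doubles coverage and preserves every beta", {
    set.seed(31)
    n <- 50
    tot <- sample(1:30, n, TRUE)
    calls <- cpgCalls("chr1", sort(sample(1e5, n)),
                      meth = vapply(tot, function(t) sample(0:t, 1), 0L),
                      total = tot)
    m <- mergeCallSets(calls, calls)
    expect_equal(mcols(m)$total_reads, 2L * mcols(calls)$total_reads)
    expect_equal(mcols(m)$beta, mcols(calls)$beta)
})

test_that("coverage filter keeps >= minTotal and pipeline order merge-then-filter matters", {
    calls <- cpgCalls("chr1", 1:4, meth = c(0, 1, 2, 3),
                      total = c(1, 2, 3, 4))
    expect_length(filterCoverage(calls, 3), 2L)   # totals 3 and 4 kept
    expect_length(filterCoverage(calls, 1), 4L)
    expect_error(filterCoverage(calls, 0), "minTotal")
    # two platforms each at 2x: only merge-then-filter retains the CpG at 3x
    a <- cpgCalls("chr1", 10, 1, 2)
    b <- cpgCalls("chr1", 10, 2, 2)
    expect_length(filterCoverage(mergeCallSets(a, b), 3), 1L)
    expect_length(mergeCallSets(filterCoverage(a, 3), filterCoverage(b, 3)),
                  0L)
    # with minTotal = 1 the two orders coincide
    expect_equal(start(filterCoverage(mergeCallSets(a, b), 1)),
                 start(mergeCallSets(filterCoverage(a, 1),
                                     filterCoverage(b, 1))))
})

test_that("bisulfite readers collapse minus-strand calls onto the plus-strand CpG", {
    f <- tempfile()
    writeLines(c("chr1\t100\t+\t3\t10", "chr1\t101\t-\t5\t10"), f)
    calls <- readBisulfite(f)
    expect_length(calls, 1L)
    expect_equal(start(calls) - 1L, 100L)
    expect_equal(mcols(calls)$meth_reads, 8L)
    expect_equal(mcols(calls)$total_reads, 20L)
    # bedGraph-like round trip
    f2 <- tempfile()
    writeBisulfite(calls, f2)
    back <- readBisulfite(f2)
    expect_equal(mcols(back)$beta, mcols(calls)$beta)
})

test_that("methylation profile binning follows the half-open window convention", {
    anchors <- GRanges("chr1", IRanges(901, 1100))   # 0-based [900,1100), mid 1000
    mk <- function(off) cpgCalls("chr1", 1000 + off, 10, 10)
    atLeft <- profileMethylation(anchors, mk(-250))
    expect_equal(profileCounts(atLeft)[1], 1L)
    atRight <- profileMethylation(anchors, mk(250))
    expect_equal(sum(profileCounts(atRight)), 0L)
    expect_true(all(is.na(profileValues(atRight))))
    inside <- profileMethylation(anchors, mk(249))
    expect_equal(profileCounts(inside)[50], 1L)
    expect_error(profileMethylation(anchors, mk(0), halfwidth = 250,
                                    binSize = 7), "binSize")
})

test_that("fully methylated data profiles at 100%, unmethylated at 0%", {
    set.seed(32)
    centers <- seq(2000, 50000, by = 2000)
    anchors <- peaks0("chrS", centers - 100, centers + 100,
                      rep(10, length(centers)))
    pos <- sort(unlist(lapply(centers, function(c) c + sample(-240:239, 30))))
    full <- cpgCalls("chrS", pos, meth = rep(8, length(pos)),
                     total = rep(8, length(pos)))
    p1 <- profileMethylation(anchors, full)
    covered <- !is.na(profileValues(p1))
    expect_true(all(profileValues(p1)[covered] == 100))
    none <- cpgCalls("chrS", pos, meth = rep(0, length(pos)),
                     total = rep(8, length(pos)))
    expect_true(all(profileValues(profileMethylation(anchors, none))[covered]
                    == 0))
})

test_that("planted regional beta is recovered within the binomial envelope", {
    set.seed(33)
    centers <- seq(1000, 2e5, by = 1000)
    anchors <- peaks0("chrS", centers - 250, centers + 250,
                      rep(1, length(centers)))
    pos <- sort(unlist(lapply(centers, function(c) c + sample(-250:249, 5))))
    depth <- 20L
    meth <- rbinom(length(pos), depth, 0.3)
    calls <- cpgCalls("chrS", pos, meth, rep(depth, length(pos)))
    prof <- profileMethylation(anchors, calls)
    v <- profileValues(prof); k <- profileCounts(prof)
    covered <- k > 0
    # per-bin 99.7% (3 SE) binomial envelope around 30%
    se <- 100 * sqrt(0.3 * 0.7 / (depth * k[covered]))
    inBand <- abs(v[covered] - 30) <= 3 * se
    expect_gte(mean(inBand), 0.97)
})

test_that("beta classification uses the printed boundaries and partitions [0,100]", {
    expect_equal(classifyBeta(c(19.999, 20, 60, 60.001, 0, 100)),
                 c("low", "medium", "medium", "high", "low", "high"))
    # the printed class assignments for the reported motifs
    expect_equal(classifyBeta(c(43, 55, 63, 73)),
                 c("medium", "medium", "high", "high"))
    grid <- seq(0, 100, by = 0.25)
    cls <- classifyBeta(grid)
    expect_true(all(cls %in% c("low", "medium", "high")))
    expect_equal(sum(cls == "low") + sum(cls == "medium") +
                     sum(cls == "high"), length(grid))
    expect_false(is.unsorted(match(cls, c("low", "medium", "high"))))
    expect_error(classifyBeta(101), "beta")
    expect_error(classifyBeta(-1), "beta")
})

test_that("per-motif methylation aggregates covered CpGs and flags uncovered motifs", {
    hits <- data.frame(chrom = "chr1", start0 = c(100, 500), end0 = c(104, 504))
    calls <- cpgCalls("chr1", c(100, 102), meth = c(4, 23),
                      total = c(10, 50))   # betas 40 and 46
    mm <- motifMethylation(hits, calls)
    expect_equal(mm$beta[1], 43)
    expect_equal(mm$class[1], "medium")
    expect_equal(mm$n_cpg[1], 2L)
    expect_equal(mm$class[2], "uncovered")
    expect_true(is.na(mm$beta[2]))
    # coverage-weighted option
    mmW <- motifMethylation(hits, calls, weighted = TRUE)
    expect_equal(mmW$beta[1], 100 * (4 + 23) / 60)
})

test_that("methylation-vs-rank pairs motifs with their containing peak only", {
    pk <- peaks0("chr1", c(0, 1000), c(200, 1200), height = c(50, 10))
    calls <- cpgCalls("chr1", c(100, 102, 500), meth = c(8, 8, 1),
                      total = c(10, 10, 10))
    mm <- motifMethylation(data.frame(chrom = "chr1",
                                      start0 = c(100, 500),
                                      end0 = c(104, 504)), calls)
    mv <- methylationVsRank(pk, mm)
    expect_equal(nrow(mv), 1L)   # motif at 500 is outside every peak
    expect_equal(mv$height, 50)
    expect_equal(mv$beta, 80)
})

test_that("tall unmethylated / short methylated structure shows in rank-beta pairs", {
    set.seed(34)
    n <- 60
    centers <- seq(1000, n * 1000, by = 1000)
    tall <- seq_len(n) <= n / 2
    h <- ifelse(tall, sample(60:100, n, TRUE), sample(5:20, n, TRUE))
    pk <- peaks0("chrS", centers - 100, centers + 100, h)
    beta <- ifelse(tall, 0.03, 0.8)
    depth <- 30L
    meth <- rbinom(n, depth, beta)
    calls <- cpgCalls("chrS", centers, meth, rep(depth, n))
    mm <- motifMethylation(data.frame(chrom = "chrS", start0 = centers - 2,
                                      end0 = centers + 2), calls)
    mv <- methylationVsRank(pk, mm)
    topHalf <- mv$rank <= stats::median(mv$rank)
    expect_lt(mean(mv$beta[topHalf]), mean(mv$beta[!topHalf]))
})

test_that("cross-cell methylation summarises covered motif betas as box-plot stats", {
    mm <- data.frame(beta = c(0, 10, 20, 30, 40))
    cc <- crossCellMethylation(mm)
    expect_equal(cc$n, 5L)
    expect_equal(unname(cc$stats["median"]), 20)
    expect_equal(unname(cc$stats[c("min", "max")]), c(0, 40))
    empty <- crossCellMethylation(data.frame(beta = NA_real_))
    expect_equal(empty$n, 0L)
    expect_null(empty$stats)
})
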