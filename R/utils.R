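# Shared internal helpers: coordinate conversions and seed fan-out.

# 0-based midpoint of a GRanges interval: for the half-open form [s0, e0)
# this is floor((s0 + e0) / 2); GRanges is 1-based closed so s0 = start - 1,
# e0 = end.
.midpoint0 <- function(gr) {
    (start(gr) - 1L + end(gr)) %/% 2L
}

# GRanges from 0-based half-open coordinates
.gr0 <- function(chrom, start0, end0, ...) {
    chrom <- rep(as.character(chrom), length.out = base::length(start0))
    GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

# Each generator draws from its own substream derived from one global seed,
# so adding a generator never perturbs the draws of an existing one.
.substream_seed <- function(seed, stream) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    offsets <- c(genome = 101L, peaks = 211L, bisulfite = 307L,
                 tags = 401L, expression = 503L, study = 601L)
    if (!stream %in% names(offsets))
        stop("unknown generator stream: ", stream)
    as.integer((as.numeric(seed) * 1103L + offsets[[stream]]) %% 2147483647)
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# overlapsAny across sets that may have disjoint chromosome universes;
# GenomeInfoDb's seqlevel warning is expected there, not actionable
.olap <- function(query, subject, ...) {
    withCallingHandlers(
        overlapsAny(query, subject, ...),
        warning = function(w) {
            if (grepl("sequence levels", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
}

.subsetPeaks <- function(x, i) {
    src <- metadata(x)$source
    gr <- as(x, "GRanges")[i]
    if (length(gr) == 0L) {
        mcols(gr)$height <- numeric(0)
        return(PeakSet(gr, source = src))
    }
    PeakSet(gr, source = src)
}
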