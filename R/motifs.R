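# IUPAC motif scanning and motif-anchored peak operations.
#
# Matching semantics, chosen to be conservative against assembly-gap
# artifacts: an ambiguity code in the *motif* matches its IUPAC base set
# (N = A/C/G/T), while any non-ACGT character in the *genome* matches
# nothing, so a peak spanning an N-gap can never yield a spurious hit.

# bitmask encoding: A=1, C=2, G=4, T=8
.IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

.motifMask <- function(pattern) {
    chars <- strsplit(toupper(pattern), "")[[1L]]
    if (length(chars) == 0L)
        stop("motif pattern must be non-empty")
    bad <- setdiff(chars, names(.IUPAC_MASK))
    if (length(bad))
        stop("invalid IUPAC character(s) in motif: ",
             paste(unique(bad), collapse = ", "))
    unname(.IUPAC_MASK[chars])
}

# subject encoding: ACGT get their bit, anything else (incl. N) gets 0
.subjectCode <- function(sequence) {
    chars <- strsplit(toupper(as.character(sequence)), "")[[1L]]
    code <- .IUPAC_MASK[chars]
    code[is.na(code) | !chars %in% c("A", "C", "G", "T")] <- 0L
    unname(code)
}

# complement of a bitmask: swap A<->T and C<->G bits, then callers reverse
.complementMask <- function(mask) {
    bitwOr(bitwOr(bitwShiftL(bitwAnd(mask, 1L), 3L),
                  bitwShiftR(bitwAnd(mask, 8L), 3L)),
           bitwOr(bitwShiftL(bitwAnd(mask, 2L), 1L),
                  bitwShiftR(bitwAnd(mask, 4L), 1L)))
}

.isPalindromic <- function(mask) {
    identical(mask, rev(.complementMask(mask)))
}

# all start offsets (0-based) where the masked pattern matches
.maskScan <- function(code, mask) {
    n <- length(code)
    k <- length(mask)
    if (n < k) return(integer(0))
    hit <- rep(TRUE, n - k + 1L)
    for (j in seq_len(k)) {
        hit <- hit & bitwAnd(code[j:(n - k + j)], mask[j]) > 0L
        if (!any(hit)) return(integer(0))
    }
    which(hit) - 1L
}

#' Scan a DNA sequence for an IUPAC motif
#'
#' Reports every (possibly overlapping) occurrence of `pattern` in
#' `sequence`. With `bothStrands = TRUE`, minus-strand occurrences are
#' found by matching the reverse complement of the pattern and reported in
#' plus-strand coordinates; for a self-reverse-complementary pattern the
#' coincident plus and minus hits are collapsed to a single `+` hit.
#'
#' Ambiguity codes in the pattern match their IUPAC base sets (`N` matches
#' A/C/G/T); `N` or any other non-ACGT character in the sequence matches
#' nothing.
#'
#' @param sequence a DNA string (character or `DNAString`),
#'   case-insensitive.
#' @param pattern an IUPAC motif string.
#' @param bothStrands scan the minus strand too (default TRUE).
#' @param motifName name recorded with each hit.
#' @param chrom chromosome name for the hit coordinates.
#' @return a `data.frame` with columns `chrom`, `start0` (0-based),
#'   `end0` (exclusive), `strand`, `motif`, `matched` (the plus-strand
#'   genomic sequence of the hit).
#' @examples
#' scanIupac("TCCTGCAATT", "TCCTGCNA")   # N matches A
#' scanIupac("CGCGCG", "CGCG")           # overlapping hits at 0 and 2
#' @export
scanIupac <- function(sequence, pattern, bothStrands = TRUE,
                      motifName = pattern, chrom = NA_character_) {
    mask <- .motifMask(pattern)
    code <- .subjectCode(sequence)
    k <- length(mask)
    seqchars <- strsplit(toupper(as.character(sequence)), "")[[1L]]
    mk <- function(pos0, strand) {
        if (!length(pos0))
            return(data.frame(chrom = character(0), start0 = integer(0),
                              end0 = integer(0), strand = character(0),
                              motif = character(0), matched = character(0)))
        data.frame(chrom = chrom, start0 = pos0, end0 = pos0 + k,
                   strand = strand, motif = motifName,
                   matched = vapply(pos0, function(p)
                       paste(seqchars[(p + 1L):(p + k)], collapse = ""), ""))
    }
    fwd <- mk(.maskScan(code, mask), "+")
    if (!bothStrands || .isPalindromic(mask)) {
        out <- fwd
    } else {
        rcmask <- rev(.complementMask(mask))
        rev_ <- mk(.maskScan(code, rcmask), "-")
        out <- rbind(fwd, rev_)
    }
    out[order(out$start0, out$strand), , drop = FALSE]
}

#' Annotate peaks with motif presence
#'
#' Scans only the sequence contained within each peak (no flank) for each
#' motif, and reports per-peak presence plus the fraction of peaks with at
#' least one hit per motif.
#'
#' @param peaks a [PeakSet].
#' @param genome a named `DNAStringSet` (one entry per chromosome), e.g.
#'   from [Biostrings::readDNAStringSet()].
#' @param motifs named character vector of IUPAC patterns (names are motif
#'   labels; unnamed patterns are labelled by themselves).
#' @param bothStrands scan both strands (default TRUE).
#' @return a list with `presence`, a logical matrix (peaks x motifs);
#'   `fraction`, the named per-motif fraction of peaks with a hit; and
#'   `hits`, a `data.frame` of all hits in genomic coordinates with a
#'   `peak` index column.
#' @export
annotateMotifPresence <- function(peaks, genome, motifs, bothStrands = TRUE) {
    motifs <- stats::setNames(as.character(motifs), names(motifs))
    if (is.null(names(motifs)))
        names(motifs) <- motifs
    names(motifs)[names(motifs) == ""] <- motifs[names(motifs) == ""]
    missing <- setdiff(unique(as.character(seqnames(peaks))), names(genome))
    if (length(missing)) {
        off <- which(as.character(seqnames(peaks)) %in% missing)
        stop("chromosome(s) absent from genome: ",
             paste(missing, collapse = ", "), " (peaks ",
             paste(utils::head(off, 5L), collapse = ", "),
             if (length(off) > 5L) ", ..." else "", ")")
    }
    presence <- matrix(FALSE, nrow = length(peaks), ncol = length(motifs),
                       dimnames = list(NULL, names(motifs)))
    allhits <- list()
    for (i in seq_along(peaks)) {
        chr <- as.character(seqnames(peaks))[i]
        seq <- as.character(Biostrings::subseq(genome[[chr]],
                                               start(peaks)[i],
                                               end(peaks)[i]))
        for (m in seq_along(motifs)) {
            h <- scanIupac(seq, motifs[[m]], bothStrands = bothStrands,
                           motifName = names(motifs)[m], chrom = chr)
            if (nrow(h)) {
                presence[i, m] <- TRUE
                h$start0 <- h$start0 + start(peaks)[i] - 1L
                h$end0 <- h$end0 + start(peaks)[i] - 1L
                h$peak <- i
                allhits[[length(allhits) + 1L]] <- h
            }
        }
    }
    hits <- if (length(allhits)) do.call(rbind, allhits)
            else data.frame(chrom = character(0), start0 = integer(0),
                            end0 = integer(0), strand = character(0),
                            motif = character(0), matched = character(0),
                            peak = integer(0))
    list(presence = presence,
         fraction = colMeans(presence),
         hits = hits)
}

#' Re-anchor peaks on a motif occurrence
#'
#' Peaks with at least one motif hit are re-centered at the midpoint of the
#' hit closest to the original peak midpoint (ties resolved to the leftmost
#' hit); peaks without hits are dropped. Output intervals are
#' `[anchor - halfwidth, anchor + halfwidth)` in 0-based coordinates.
#'
#' @param peaks a [PeakSet].
#' @param hits a hit `data.frame` as returned by [annotateMotifPresence()]
#'   (genomic 0-based `start0`/`end0` plus a `peak` index column).
#' @param halfwidth positive half-window in bp.
#' @return a `GRanges` of recentered windows with metadata columns `anchor0`
#'   (the 0-based anchor) and `peak` (index into `peaks`).
#' @export
recenterOnMotif <- function(peaks, hits, halfwidth) {
    if (halfwidth <= 0)
        stop("'halfwidth' must be positive")
    keep <- sort(unique(hits$peak))
    anchors0 <- integer(0)
    chroms <- character(0)
    for (i in keep) {
        h <- hits[hits$peak == i, , drop = FALSE]
        mid0 <- (h$start0 + h$end0) %/% 2L
        pmid0 <- .midpoint0(peaks[i])
        best <- order(abs(mid0 - pmid0), h$start0)[1L]
        anchors0 <- c(anchors0, mid0[best])
        chroms <- c(chroms, as.character(seqnames(peaks))[i])
    }
    out <- .gr0(chroms, pmax(anchors0 - halfwidth, 0L), anchors0 + halfwidth)
    mcols(out)$anchor0 <- anchors0
    mcols(out)$peak <- keep
    out
}

#' Hypergeometric motif enrichment test
#'
#' Compares the motif-hit rate in a foreground peak set against a
#' background set. The p-value is the upper-tail hypergeometric probability
#' of observing at least `fgHits` motif-containing peaks when drawing
#' `fgTotal` peaks from the pooled population of `fgTotal + bgTotal` peaks
#' containing `fgHits + bgHits` motif-positive ones.
#'
#' @param fgHits,fgTotal foreground hit and total counts.
#' @param bgHits,bgTotal background hit and total counts.
#' @return a list with `ratio` (foreground rate over background rate; `Inf`
#'   when the background rate is zero and the foreground rate positive) and
#'   `p.value`.
#' @examples
#' motifEnrichmentTest(10, 10, 0, 10)$p.value  # 1 / choose(20, 10)
#' @export
motifEnrichmentTest <- function(fgHits, fgTotal, bgHits, bgTotal) {
    stopifnot(fgHits >= 0, bgHits >= 0, fgHits <= fgTotal, bgHits <= bgTotal)
    fgRate <- fgHits / fgTotal
    bgRate <- bgHits / bgTotal
    ratio <- if (bgRate == 0) {
        if (fgRate == 0) NaN else Inf
    } else fgRate / bgRate
    K <- fgHits + bgHits
    N <- fgTotal + bgTotal
    p <- stats::phyper(fgHits - 1, K, N - K, fgTotal, lower.tail = FALSE)
    list(ratio = ratio, p.value = p)
}
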