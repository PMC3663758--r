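#' Read a BED-like file of scored peaks
#'
#' Parses a tab- or whitespace-separated BED-like file (chrom, start, end,
#' score, ...) into a [PeakSet]. BED coordinates are 0-based half-open and
#' are converted to the 1-based closed GRanges convention on input. Ranks
#' are assigned by descending score with ties broken by (chrom, start);
#' input order is not assumed sorted.
#'
#' @param path path to the file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param scoreColumn 1-based column index holding the peak score / summit
#'   tag height (default 4, the BED score column). If the file has fewer
#'   columns every peak gets height 0.
#' @param source provenance string stored in the result's metadata.
#' @return a [PeakSet].
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\t50", "chr1\t300\t400\t90"), bed)
#' readPeaks(bed, source = "toy")
#' @export
readPeaks <- function(path, scoreColumn = 4L, source = basename(path)) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) {
        gr <- GRanges()
        mcols(gr)$height <- numeric(0)
        return(PeakSet(gr, source = source))
    }
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed line ", lineno[which(nf < 3L)[1L]],
             " in '", path, "': fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0L)
    if (length(bad))
        stop("malformed line ", lineno[bad[1L]], " in '", path,
             "': coordinates must be non-negative integers")
    bad <- which(end0 <= start0)
    if (length(bad))
        stop("malformed line ", lineno[bad[1L]], " in '", path,
             "': end must exceed start")
    if (all(nf >= scoreColumn)) {
        height <- suppressWarnings(as.numeric(
            vapply(fields, `[[`, "", scoreColumn)))
        bad <- which(is.na(height))
        if (length(bad))
            stop("malformed line ", lineno[bad[1L]], " in '", path,
                 "': score column ", scoreColumn, " is not numeric")
    } else {
        height <- rep(0, length(chrom))
    }
    PeakSet(.gr0(chrom, start0, end0), height = height, source = source)
}

#' Write peaks as BED (chrom, start, end, score)
#'
#' @param peaks a [PeakSet] or `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
    h <- if (is(peaks, "PeakSet")) peakHeights(peaks)
         else if (!is.null(mcols(peaks)$height)) mcols(peaks)$height
         else rep(0, length(peaks))
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     score = h)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BED3 file of plain intervals (e.g. an amplified-region blacklist)
#'
#' @param path path to a BED3+ file.
#' @return a `GRanges`.
#' @export
readIntervals <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    if (!length(lines)) return(GRanges())
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 3L))
        stop("'", path, "' has lines with fewer than 3 columns")
    .gr0(vapply(fields, `[[`, "", 1L),
         as.integer(vapply(fields, `[[`, "", 2L)),
         as.integer(vapply(fields, `[[`, "", 3L)))
}

#' Read transcription start sites from refFlat or BED12 transcript models
#'
#' For `+` strand transcripts the TSS is the 0-based transcript start; for
#' `-` strand transcripts it is the last transcribed base (`end - 1` in
#' 0-based half-open coordinates).
#'
#' @param path path to a refFlat (geneName, name, chrom, strand, txStart,
#'   txEnd, ...) or BED12 (chrom, start, end, name, score, strand, ...)
#'   file; the format is auto-detected from the strand column position.
#' @return a width-1 `GRanges` of TSS positions with metadata columns
#'   `gene_id` and strand set.
#' @export
readTss <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    if (!length(lines))
        return(GRanges(gene_id = character(0)))
    fields <- strsplit(lines, "\t")
    f1 <- fields[[1L]]
    isRefFlat <- length(f1) >= 6L && f1[[4L]] %in% c("+", "-")
    if (isRefFlat) {
        gene <- vapply(fields, `[[`, "", 1L)
        chrom <- vapply(fields, `[[`, "", 3L)
        strand <- vapply(fields, `[[`, "", 4L)
        s0 <- as.integer(vapply(fields, `[[`, "", 5L))
        e0 <- as.integer(vapply(fields, `[[`, "", 6L))
    } else {
        if (length(f1) < 6L || !f1[[6L]] %in% c("+", "-"))
            stop("'", path, "' is neither refFlat nor stranded BED")
        chrom <- vapply(fields, `[[`, "", 1L)
        s0 <- as.integer(vapply(fields, `[[`, "", 2L))
        e0 <- as.integer(vapply(fields, `[[`, "", 3L))
        gene <- vapply(fields, `[[`, "", 4L)
        strand <- vapply(fields, `[[`, "", 6L)
    }
    tss0 <- ifelse(strand == "+", s0, e0 - 1L)
    gr <- .gr0(chrom, tss0, tss0 + 1L, strand = strand)
    mcols(gr)$gene_id <- gene
    gr
}

#' Read stranded tag alignments from BED6
#'
#' Each record contributes its 5' position: the BED start for `+` tags, the
#' last base (`end - 1`, 0-based) for `-` tags.
#'
#' @param path path to a BED6 file.
#' @return a width-1 `GRanges` of 5' tag positions with strand set.
#' @export
readTags <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    if (!length(lines)) return(GRanges())
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 6L))
        stop("'", path, "' must be BED6 (strand required)")
    chrom <- vapply(fields, `[[`, "", 1L)
    s0 <- as.integer(vapply(fields, `[[`, "", 2L))
    e0 <- as.integer(vapply(fields, `[[`, "", 3L))
    strand <- vapply(fields, `[[`, "", 6L)
    if (!all(strand %in% c("+", "-")))
        stop("'", path, "' has tags without +/- strand")
    p0 <- ifelse(strand == "+", s0, e0 - 1L)
    .gr0(chrom, p0, p0 + 1L, strand = strand)
}
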