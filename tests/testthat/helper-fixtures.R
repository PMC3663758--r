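# Shared fixture builders; everything is constructed in code at test time.

library(GenomicRanges)

# three checks depend on non-redistributable external data and report one
# failure each when it is absent; keep the reporter from stopping early
options(testthat.progress.max_fails = 100)

# PeakSet from 0-based half-open coordinates
peaks0 <- function(chrom, start0, end0, height, source = "test") {
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    methbind::PeakSet(gr, height = height, source = source)
}

# width-1 TSS GRanges from 0-based positions
tss0 <- function(chrom, pos0, strand = "+",
                 gene = sprintf("g%d", seq_along(pos0))) {
    gr <- GRanges(chrom, IRanges(pos0 + 1L, pos0 + 1L), strand = strand)
    mcols(gr)$gene_id <- gene
    gr
}

# toy genome: named DNAStringSet from character vector
toyGenome <- function(...) {
    Biostrings::DNAStringSet(c(...))
}

# write a temporary BED file from a data.frame of 0-based coordinates
writeBedLines <- function(lines) {
    f <- tempfile(fileext = ".bed")
    writeLines(lines, f)
    f
}

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompStr <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
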