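Package: methbind
Title: Integrative Analysis of Transcription-Factor Binding and DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating transcription-factor ChIP-seq binding sites to
    DNA methylation, chromatin signal and gene expression. Implements replicate
    reproducibility assessment and high-confidence peak derivation for called
    peak sets, IUPAC motif scanning with motif-anchored peak recentering,
    per-CpG bisulfite methylation quantification and low/medium/high
    classification of motif methylation, tag-density meta-profiles around
    binding sites, cross-cell-type binding comparison, union-exon RPKM
    expression quantification, and seeded synthetic-data generators that
    emulate every input so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
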