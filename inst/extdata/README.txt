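Optional external inputs for the three published-data checks in
tests/testthat/test-acceptance.R. These files are not redistributable with
the package; place them here to enable the checks:

  kaiso_hc_GM12878.bed  high-confidence GM12878 Kaiso peaks (BED: chrom,
                        start, end, score), 1,648 records
  kaiso_hc_K562.bed     high-confidence K562 Kaiso peaks (post
                        amplified-region filtering), 3,082 records
  hg19.fa               hg19 genome sequence, FASTA, UCSC chromosome names

All other fixtures are generated in code at test time.
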