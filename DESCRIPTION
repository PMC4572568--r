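Package: annoshift
Title: Local Annotation Shifting Enrichment Tests for Trait-Associated Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether trait-associated variants overlap a genomic
    annotation more often than expected under a locus-local null obtained by
    circularly shifting annotation intervals within each locus. Includes a
    stratified test that separates the contributions of colocalizing
    annotations, the delta-overlap effect size, per-locus overlap scores for
    prioritizing loci, a SNP-matching baseline test, linkage-disequilibrium
    utilities (proxy expansion, tag selection, independence pruning), and a
    synthetic-genome simulation harness for power, type-I-error and
    causal-proportion studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
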