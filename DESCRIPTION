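Package: otwgs
Title: Whole-Genome Off-Target Adjudication for CRISPR-Edited Plant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether mutations found by whole-genome
    sequencing of CRISPR-edited plants are true nuclease off-target events
    or background variation. Implements multi-caller variant consensus with
    allele-frequency filtering, subtraction of pre-existing and
    tissue-culture/transformation background using control cohorts,
    protospacer+PAM genome scanning with seed-mismatch and bulge-aware
    flank alignment, replicate-based validation of off-target indels, and
    mutation rate, spectrum, allele-frequency and feature-enrichment
    profiling. Includes a synthetic-cohort generator that emulates the
    statistical structure of edited-plant sequencing studies (class-specific
    mutation loads, heterozygous-like allele frequencies, planted guide
    edits, and noisy per-caller views of a truth set) so the whole pipeline
    can be exercised and validated end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
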