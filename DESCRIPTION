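Package: gitax
Title: Genomic Instability Scar Scores and Subtype Classification for
    Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes homologous-recombination-deficiency (HRD) chromosomal
    scar scores (telomeric allelic imbalance, large-scale state transitions,
    HRD-LOH) from allele-specific copy-number segments, mutation-level
    features (SBS96 catalogs, tumor mutational burden, APOBEC TCW fraction,
    kataegis clusters, signature refitting by non-negative least squares,
    CN48 and SV32 encodings), and classifies tumor genomes into four
    genomic-instability subtypes (HRD, MUT, CN, GS) by fixed or cohort-mean
    thresholds. Includes readers for segment TSV, VCF, BEDPE and
    COSMIC-style signature matrices, a germline-variant inclusion filter,
    association statistics, and a deterministic synthetic-cohort generator
    with ground-truth archetype labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    withr,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
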