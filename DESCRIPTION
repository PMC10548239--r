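Package: xburden
Title: Hemizygous X-Chromosome Variant Burden and Mosaicism Analysis for
    Turner Syndrome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exome-wide variant analysis in Turner syndrome
    (45,X and related karyotypes) and comparison cohorts: parallel
    standard and somatic-mosaic variant filtering, per-sample exome
    variability profiling with rank-based group comparison, gene- and
    variant-level burden testing of common hemizygous X-chromosome
    variants against clinical phenotypes (exact conditional tests,
    conditional maximum-likelihood odds ratios, Bonferroni correction),
    autosomal candidate-gene allele-frequency replication, SNP-array
    B-allele-frequency and log R ratio mosaic cell-line fraction
    estimation, two-proportion power calculations, and a synthetic
    cohort generator so the whole pipeline is testable without access
    to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
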