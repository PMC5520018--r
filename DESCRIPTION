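Package: transload
Title: Transancestral Case-Control Association and Genetic-Load Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for multi-ancestry case-control association studies
    on dense genotyping arrays: SNP and sample quality control with exact
    Hardy-Weinberg tests, admixture-factor covariates and genomic control;
    single-SNP logistic association with additive/dominant/recessive model
    selection and tiered significance; sample-size-weighted inverse-normal
    meta-analysis across ancestries with heterogeneity tests; HLA allele
    dosage association, stepwise multi-locus modelling, compound risk-allele
    heterozygosity tests and amino-acid clustering of allele protein
    sequences; genetic risk-allele load construction with sliding-window
    odds ratios and tests for supra-additive (accelerating) risk; risk-allele
    frequency clustering and admixture-deviation profiling; and a 0-15
    biological annotation score with CpG-site determination and eQTL proxy
    joins. Includes a synthetic multi-ancestry cohort generator so the whole
    pipeline runs end-to-end without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
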