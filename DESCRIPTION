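Package: genmediate
Title: Genotype-Biomarker Association and Mediation Analysis with
    Suppression Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Candidate-gene association and mediation analysis for paired
    acute-phase biomarkers (C-reactive protein and serum amyloid A).
    Provides EM haplotype frequency estimation from unphased genotypes,
    Hardy-Weinberg and linkage-disequilibrium diagnostics, additive and
    dominant genotype coding (including triallelic recoding),
    covariate-adjusted linear models with Bonferroni correction and partial
    correlation, quartile subgroup analysis, and a four-criterion mediation
    framework with the Sobel delta-method test that classifies mediation
    versus suppression effects. A seeded synthetic-cohort generator with a
    structural path model makes the full pipeline reproducible without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
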