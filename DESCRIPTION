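Package: pcosmir
Title: Circulating miRNA qPCR Biomarker Analysis for Metabolic Syndrome in PCOS
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for serum circulating microRNA biomarker
    studies built around TaqMan low-density qPCR arrays. Provides Ct-table
    parsing, detection filtering, global mean normalization and 2^-ddCt
    relative quantification, NormFinder-style reference stability scoring and
    standard-curve quantification; derivation of endocrine and metabolic
    clinical variables (mass-action free testosterone, HOMA-IR, IDF metabolic
    syndrome rule, androgen stratification); covariate-adjusted differential
    and correlation statistics (t-test/ANOVA with Tukey, binary and
    multinomial logistic odds ratios, partial Pearson correlations, volcano
    tables, Fisher's exact test, power calculations); and ROC analysis of
    single markers and logistic multi-marker panels, including DeLong
    confidence intervals and paired AUC comparison. A seeded synthetic-cohort
    generator emulating a three-group case-control design (controls,
    normoandrogenic and hyperandrogenic polycystic ovary syndrome) makes the
    whole pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
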