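Package: umevol
Title: Clonal Evolution Analysis of Uveal Melanoma Driver Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the early genetic evolution of uveal
    melanoma from targeted sequencing of the seven recurrent driver genes
    (GNAQ, GNA11, CYSLTR2, PLCB4, BAP1, SF3B1, EIF1AX). Estimates tumor
    purity from the founder Gq mutation, computes purity-corrected variant
    allele frequencies and cancer cell fractions under gene-specific allelic
    models, calls chromosome-3p loss of heterozygosity (copy loss versus
    isodisomy versus retention) from a 74-locus B-allele-frequency/read-depth
    panel against a panel of normals with automated confidence scoring,
    classifies variants with a pathogenicity rule engine over precomputed
    annotation scores, and runs the cohort statistics (association scans with
    the chi-square/Fisher switching rule, Kaplan-Meier/log-rank, Cox models,
    3:1 propensity matching, log-rank power simulation). A seeded synthetic
    cohort generator with retained ground truth supports estimator validation
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
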