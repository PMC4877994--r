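Package: methaccord
Title: Agreement Analysis of LINE-1 and LUMA Global DNA Methylation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for laboratory method-comparison studies of the two most
    widely used global DNA methylation biomarkers: pyrosequencing of CpG
    sites in the LINE-1 retrotransposon promoter and the luminometric
    methylation assay (LUMA) based on HpaII/MspI isoschizomer digestion.
    Quantifies percent methylation from pyrogram peak heights with quality
    control and two-point control calibration, computes per-tissue agreement
    statistics (repeated-measures ANOVA, Wilcoxon signed-rank, bootstrap
    Spearman correlation, and Bland-Altman limits of agreement with fixed
    and proportional bias), models the distribution of interassay
    differences with a univariate Gaussian mixture fitted against a Pareto
    density estimate with Bayes decision boundaries and a tissue-predictive
    decision tree, fits subset-specific linear calibration models by
    stepwise likelihood-ratio model building with bootstrap confidence
    intervals, and compares treatment effect sizes (Cohen's d) across the
    two assays.  A calibrated synthetic-data generator emulates the joint
    distribution of paired assay readings in treated MCF7 and SHSY5Y cell
    lines and human whole blood so every stage is testable without access
    to the original laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
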