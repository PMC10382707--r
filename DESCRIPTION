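Package: audiogain
Title: Evoked-Potential Audiometry, Central Auditory Gain, and Cortical
    Cell-Density Analysis
Version: 1.0.0
Authors@R:
    person("Robin", "Ingham", email = "r.ingham@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of auditory brainstem responses
    (ABR) and cortical auditory evoked potentials (AEP) in rodent hearing
    studies, together with quantitative histology of cortical interneuron
    density. Provides zero-phase Butterworth preprocessing and extraction of
    ABR wave I and AEP P1/N1/P2 features, central auditory gain ratios,
    automated ABR threshold detection, hearing-impairment classification
    against a wild-type reference cutoff, laminar depth normalization and
    binning of cell centroids, planar cell-density estimation over polygonal
    regions of interest, and the accompanying statistical battery (Wilcoxon
    rank-sum and signed-rank tests, Spearman rank correlation, t tests, and
    one-way ANOVA with Fisher's LSD post hoc tests). A synthetic-cohort
    generator emulates the data structure of a two-genotype mouse study with
    bimodal per-ear hearing thresholds, so the full pipeline is testable
    without access to animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
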