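Package: smapkit
Title: Sample Mix-Up Detection and Correction for Multiplexed Quantitative Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Verifies and corrects sample identities in multiplexed isobaric
    labeling (TMT) proteomic experiments by inferring per-channel genotypes
    from variant-peptide reporter-ion intensities and matching them against a
    reference genotype panel. Implements reporter-ion preprocessing (isotope
    impurity correction, trimmed-median loading normalization, min-max
    scaling), a two-component Gaussian mixture noise model fit by EM with a
    derived minimum-signal cutoff plus signal-to-noise and minor-allele
    frequency peptide filters, quartile-based genotype calling with a
    dosage-aware two-class rule, concordance (Cscore) and specificity
    (delta-Cscore) scoring with swap-topology classification, and a
    genotype-shuffling simulation for assessing how many reliable genotypes
    identity recovery requires.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
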