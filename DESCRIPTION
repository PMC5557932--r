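Package: agewas
Title: Epigenome-Wide Association Analysis of Aging with Permutation FWER and Twin-Cohort Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for epigenome-wide association studies (EWAS) of
    chronological age on Illumina 450K-like DNA methylation data. Provides the
    beta-to-M logit transform, per-CpG ordinary least squares adjusted for blood
    cell composition, minP permutation estimation of the family-wise error rate,
    linear mixed-model replication across independent twin cohorts with
    direction-concordance criteria, contingency characterization of replicated
    CpGs by gene region and CpG-island relation, and hypergeometric
    over-representation analysis of nearest genes against GMT gene sets. A
    synthetic-data module generates cohorts with the statistical structure the
    analysis assumes (repeated measures, twin pairs, planted age effects,
    Dirichlet cell compositions) so the full pipeline is testable without any
    array download.
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
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
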