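Package: gutcadence
Title: Longitudinal Infant Gut Microbiome Time-Series Analysis and
    Sampling-Cadence Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compositional analysis of dense infant gut microbiome time
    series: prevalence/abundance filtering, count-zero-multiplicative zero
    replacement and centered log-ratio (CLR) transformation; Shannon
    diversity series and weekly coefficient-of-variation profiling;
    permutation-based circular binary segmentation of the diversity series
    into homogeneous microbial diversity (HMD) periods; nonparametric
    event-window testing (Mann-Whitney, Kruskal-Wallis with Dunn post hoc,
    Friedman with Conover post hoc) with Benjamini-Hochberg adjustment and
    PERMANOVA on Aitchison distances; rule-based colonizer-archetype
    classification; and a weekly-downsampling experiment quantifying how
    sparse sampling degrades detection of transient taxa and event-driven
    shifts. A Dirichlet-multinomial simulator generates infant-gut count
    tables with planted colonizer trajectories and event effects so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
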