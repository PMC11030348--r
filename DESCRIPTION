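Package: spothits
Title: Dual-Control Hit Calling for Region-Targeted Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spot-based spatial transcriptomics of a
    chemogenetic (DREADD) mouse study design with a specificity control arm.
    Provides a negative-binomial synthetic-data generator emulating
    Visium-style hexagonal capture-area lattices with marker-defined brain
    regions; marker-rule disc selection with glial-contamination exclusion;
    a normalization suite (median, quantile, Q3, negative-probe background,
    library size) with GeoMx-style segment QC and an MA-correlation /
    Kolmogorov-Smirnov normalization-selection diagnostic; per-region
    differential expression ranked by fold-change score (FCS) and
    signal-to-noise score (SNS) with dual-control hit intersection;
    principal-component group structure; section-normalized activity-score
    comparison; and cross-species directional-congruence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    cluster,
    optparse,
    ggplot2
Config/testthat/edition: 3
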