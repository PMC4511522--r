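Package: phenoz
Title: Bootstrap Z-Score Harmonization of Multi-Assay Mutant Phenotyping Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous plant-phenotyping experiments on a mutant
    collection into a single comparable effect matrix. Each assay's
    genotype-versus-wild-type comparison is converted to a signed Z statistic
    (two-sample contrasts, tie-corrected Mann-Whitney, or a random-intercept
    mixed model for multi-experiment time courses), commensurated across
    experiments by bootstrap resampling every condition cell to a common sample
    size, adjusted for multiplicity by sign-preserving Benjamini-Hochberg
    correction carried out in Z-space, and summarised as tiered significance
    calls. Includes the two hierarchical clustering recipes used for integrated
    phenotype heatmaps (Ward/Euclidean and complete linkage on 1-Pearson
    distance), a synthetic multi-assay phenomics generator with known planted
    effects for validation, and a reproducible end-to-end pipeline with YAML
    configuration and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    multcomp,
    ape,
    mclust
Config/testthat/edition: 3
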