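Package: gliaquant
Title: Quantification of Regional Microglia Depletion from Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify microglia depletion across brain regions from
    fluorescence and histology images. Detects individual cells in 3D
    two-photon stacks and computes volumetric densities and per-cell sizes;
    counts chromogenic IHC-positive cells with minima-controlled watershed
    splitting and normalizes to region-of-interest area; measures in situ
    hybridization signal as percent of tissue area stained; and implements the
    statistical layer used in depletion studies (depletion percentages,
    one-way ANOVA with Dunnett's many-to-one post hoc test,
    Kolmogorov-Smirnov comparison of binned intensity distributions, and
    weighted quadratic calibration-curve quantitation with back-calculation).
    A seeded synthetic-data generator produces image stacks, slides, and
    multi-animal cohorts with exact ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    multcomp,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
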