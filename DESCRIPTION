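Package: oxynet
Title: Density-Dependent Oxylipin Production and Diatom Co-Variation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for particulate oxylipin (linear oxygenated
    fatty acid, LOFA) production in natural diatom communities. Provides
    internal-standard quantification of targeted oxylipin peak tables and
    per-litre / per-cell / per-carbon normalization, balanced ANOSIM, SIMPER
    and non-metric multidimensional scaling of community composition,
    log-log density-dependence regressions with VIF screening and backward
    elimination, normalization and regression of lipoxygenase transcript
    abundances against diatom metagenome abundances, and chemically
    annotated Spearman co-occurrence networks over salinity-defined
    water-mass windows with modularity detection and permutation null
    tests. A synthetic-data generator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
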