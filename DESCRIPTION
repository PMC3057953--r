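Package: phyloqc
Title: Signal Diagnostics for Phylogenomic Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control diagnostics for phylogenomic datasets:
    saturation quantification by regressing uncorrected on patristic
    distances, support-thresholded congruence screening of single-gene
    trees against a concatenated reference as an a-posteriori orthology
    check, missing-data profiling of supermatrices, and taxon-sampling /
    outgroup-pruning experiments. Includes a distance-based inference
    engine (p-distances with pairwise deletion, Poisson and gamma
    corrections, neighbor-joining, nonparametric bootstrap) and a
    sequence-evolution simulator supporting site-homogeneous and
    CAT-like site-heterogeneous profile-mixture models, long-branch
    attraction geometries, implanted contaminations, and masked missing
    data, so every diagnostic can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
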