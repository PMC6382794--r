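Package: morphodelim
Title: Landmark-Based Geometric Morphometrics for Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting species from 2D landmark data: generalized
    Procrustes superimposition with sliding semilandmarks and decomposition of
    bilateral (object and matching) symmetry, hierarchical Procrustes ANOVA of
    shape and centroid size with Goodall's F and permutation tests, multivariate
    allometry regression and size correction, principal component and pairwise
    discriminant analyses, two-block partial least squares with the RV
    coefficient, RV-based landmark modularity tests, and squared-change
    parsimony mapping of shapes onto a phylogeny with a permutation test of
    phylogenetic signal. Includes a seeded simulator of landmark datasets with
    nested measurement error, allometry, and directional and fluctuating
    asymmetry, emulating a multi-structure study design for cyclopoid copepods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    grDevices,
    ape,
    dplyr,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
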