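Package: phylosieve
Title: Phylogenetic Comparative Analysis for Sparse, Biased Trait Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting correlates of monotonically eroding traits
    (such as organelle genome gene counts) across broad phylogenies when
    predictor observations are sparse and biased towards false negatives.
    Includes a seeded simulator of joint predictor/response evolution on
    balanced and birth-death phylogenies with one-way observation occlusion;
    phylogenetic generalized least squares under Brownian, Pagel-lambda,
    Martins-Hansen and Grafen covariance structures with profile
    likelihood-ratio tests; Poisson regression with a phylogenetic working
    correlation fitted by generalized estimating equations; Pagel's lambda
    signal estimation; nonparametric sibling-contrast tests (exact Wilcoxon
    signed-rank and bootstrap); the Scheirer-Ray-Hare two-way rank test with
    Kruskal-Wallis fallback and clade-mean normalization; a
    sensitivity/specificity benchmarking harness; a trait-table screening
    pipeline with positive-subtree restriction, influence filtering and
    Bonferroni-coded significance profiles; and a semi-automated regex-driven
    curation tool that renders XML article dumps to interactive HTML review
    pages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
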