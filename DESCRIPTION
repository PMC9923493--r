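Package: plastrange
Title: Evolution of Phenotypic Plasticity Along Environmental Gradients and
    Reaction-Norm Analysis of Reciprocal Transplants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based, forward-in-time simulation of a range expansion
    across a one-dimensional habitat in which a quantitative trait is built
    from a nonplastic genetic component and an evolving plastic component,
    both with polygenic biallelic additive architectures. Includes in-silico
    reciprocal-transplant experiments on the evolved metapopulation, with
    rank-based reaction-norm statistics (Kruskal-Wallis omnibus, Dunn-type
    Bonferroni post hoc contrasts, Glass' delta effect sizes), a classifier
    for the qualitative transplant outcome patterns expected under low to
    very high plasticity, genotype PCA, and an analysis path for empirical
    two-population by two-salinity transplant phenotype tables backed by a
    synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
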