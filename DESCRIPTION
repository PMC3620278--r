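Package: cophylofit
Title: Procrustes Superimposition Tests of Cophylogenetic Congruence
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tests the dependence of a parasite phylogeny on its host
    phylogeny by Procrustes superimposition of principal-coordinate
    ordinations under arbitrary many-to-many host-parasite associations
    (the PACo approach). Provides the global goodness-of-fit statistic
    m2 with a row-permutation significance test, jackknife estimation of
    per-link squared residuals with one-sided confidence bounds,
    reimplementations of two rival global-fit tests (the ParaFit trace
    test and the Hommola et al. cospeciation correlation test), and a
    simulation harness for Type I error and statistical power
    experiments on random additive phylogenies. Includes superimposition
    and residual-bar graphics, broom-style tidiers, and readers for
    Newick trees, distance matrices and binary association tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    rlang,
    ape,
    generics,
    ggplot2,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
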