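Package: mutburden
Title: Birth-Death Branching Processes with Mutation Accumulation: Site
    Frequency Spectra, Division and Mutational Burden Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analytic theory for neutral mutation accumulation
    in a discrete-time birth-death branching process, as arises in growing
    tumour and clonal cell populations. Each step a uniformly chosen cell
    divides with probability beta or dies with probability delta = 1 - beta;
    daughter cells inherit parental mutations and acquire new ones under the
    infinite-sites approximation. The package maintains the dynamical
    genotype (SNP) matrix of the population and derives from it the site
    frequency spectrum (SFS), the single-cell division distribution (DD) and
    the single-cell mutational burden distribution (MBD). Exact pure-birth
    expectations (via unsigned Stirling numbers of the first kind), their
    recurrence-relation counterparts, first-order birth-death approximations,
    survival-conditioned population sizes, and the Poisson-mixture conversion
    between DD and MBD are all provided, together with an ensemble harness
    for comparing stochastic simulations against theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
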