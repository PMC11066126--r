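Package: dimerevol
Title: Evolution of Homodimers and Heterodimers After Gene Duplication
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical model of the equilibrium between homodimers and
    heterodimers formed by a pair of paralogous proteins after gene
    duplication, together with origin-fixation Monte-Carlo simulations of
    their evolution. Equilibrium concentrations of the five molecular
    species (two monomers, two homodimers, one heterodimer) are obtained
    from mass-action kinetics (a quartic polynomial in the concentration of
    one monomer), total activity is mapped to fitness through a lognormal
    function, and mutational effects on folding and binding free energies
    are drawn from correlated parametric distributions or from empirical
    per-substitution tables of the kind produced by structure-based
    mutational scanning. Includes a synthetic-table generator with a
    tunable heterodimer-favoring mutational bias, residual and enrichment
    statistics, outcome classification, and replicate-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
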