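Package: levysearch
Title: Optimal Levy Search Strategies in Heterogeneous One-Dimensional Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models random search for sparse targets on a one-dimensional
    interval with absorbing boundary targets, coupling landscape
    heterogeneity to search efficiency. Landscape heterogeneity enters
    through a probability density of searcher restart positions between
    encounters. Provides truncated power-law (Levy), exponential and
    fixed-length step models; a deterministic integral-operator solver for
    the mean distance travelled between consecutive encounters; a
    fluctuation-averaged efficiency functional with numerical location of
    the optimal Levy exponent and of the crossover from superdiffusive to
    ballistic optimal strategies; and an independent Monte Carlo simulator
    of the search process used as a verification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
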