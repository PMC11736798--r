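Package: nanofluct
Title: Density Fluctuations and Isothermal Compressibility in Nanoscale Subvolumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes particle number fluctuations and the isothermal
    compressibility of simple fluids and solids inside finite open
    subvolumes. Implements finite-volume Kirkwood-Buff integration with
    geometric weight functions, and an excluded-volume-aware modified pair
    distribution function obtained by convolving the two-particle density
    (including its diagonal part) with a finite-size particle profile
    kernel. Ships exact reference models: the one-dimensional hard-rod
    (Tonks) fluid, the three-dimensional Percus-Yevick hard-sphere fluid,
    the face-centered-cubic hard-sphere solid, and closed-form equations
    of state (Tonks, Carnahan-Starling, Percus-Yevick compressibility
    route), together with a Monte Carlo hard-rod sampler used as an
    independent oracle for window-counting fluctuation measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
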