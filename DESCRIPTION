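Package: probitab
Title: Active-Learning Surrogate Optimisation of Probiotic Tabletting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for identifying tabletting process conditions that maximise
    probiotic survival. Couples a reduced-order compaction-thermal-viability
    simulator (Drucker-Prager Cap densification work, a 1-D radial implicit
    finite-volume energy balance and a z-value thermal tolerance law) with
    Gaussian-process regression under a squared-exponential kernel, an
    active-learning loop driven by maximum-standard-deviation acquisition,
    and extraction of near-optimal process regions as 3-D alpha shapes.
    Includes Sobol and random experimental designs on the constrained
    (compression speed, precompression pressure, main compression pressure)
    space and colony-count survival-rate arithmetic for plate assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
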