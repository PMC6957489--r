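Package: fusepore
Title: Kinetic Analysis of Single Fusion-Pore Currents and smFRET Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving kinetic intermediates of exocytotic fusion
    pores from single-channel planar-bilayer recordings and single-molecule
    FRET traces. Includes continuous-time Markov simulators for pore gating
    (with Hill-type Ca2+ modulation, Bessel-filtered rendering) and for
    two-colour smFRET traces; threshold-based trace idealization with dead-time
    handling; dwell-time cumulative-distribution fitting with constrained
    exponential mixtures and AIC model selection; current-histogram Gaussian
    mixture fitting, conductance and approximate pore-diameter estimation;
    Hill dose-response fitting and Pearson chi-squared occurrence analysis;
    photobleach-step selection and FRET-state Gaussian mixture fitting; and
    small geometry calculators for nanodisc surface densities and planar-membrane
    lipid fractions.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
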