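Package: multinoise
Title: Multistage Noise Models for Neural Spike-Count Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Linear-nonlinear cascade models of binned neural spike counts in
    which response variability arises from three distinct noise sources: an
    additive Gaussian perturbation upstream of a softplus nonlinearity, a
    multiplicative source at the nonlinearity output whose variance scales
    with the mean, and an additive (optionally intermittent mixture)
    downstream source, followed by deterministic rounding and rectification
    to a spike count. Provides the exact count likelihood by numerical
    integration through the cascade, multi-start bounded Nelder-Mead maximum
    likelihood estimation, a linear-nonlinear-Poisson baseline,
    reverse-correlation preprocessing of raw stimulus/spike recordings,
    signal-to-noise and Jensen-Shannon divergence metrics, and a simulation
    harness for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
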