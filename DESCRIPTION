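Package: sgmbayes
Title: Bayesian Inference for Spectral Graph Models of Brain Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the spectral graph model (SGM) of regional brain
    oscillation spectra, a linear generative model with a closed-form
    frequency-domain solution on a structural connectome, together with
    amortized simulation-based Bayesian inference of its seven global
    biophysical parameters. Training pairs simulated from the forward model
    are used to fit a conditional mixture density network that approximates
    the posterior over reparameterized (scaled-logit) parameters for any
    observed power spectral density; posterior draws are mapped back to the
    bounded parameter space and filtered by a mesoscopic stability predicate.
    A dual-phase simulated-annealing point estimator, posterior-predictive
    reconstruction, calibration diagnostics, and the evaluation statistics
    used to compare fits (per-region spectral correlation, degree-weighted
    spatial correlation of alpha-band power, partial correlations among
    parameters) are included, along with synthetic connectome and subject
    generators for end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
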