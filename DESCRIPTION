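Package: prfmap
Title: Population Receptive Field Modeling for fMRI and Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward population receptive field (pRF) models for visually
    driven responses to bar-sweep mapping stimuli. Builds binary effective
    stimuli in visual-degree coordinates, evaluates four pRF models (a
    positive-constrained linear Gaussian, an unconstrained linear Gaussian,
    a difference-of-Gaussians, and a compressive spatial summation model),
    convolves predictions with monkey or human hemodynamic response
    functions, and fits models to BOLD, multi-unit activity (MUA), or local
    field potential (LFP) band-power responses by multi-start nonlinear
    least squares with split-half cross-validated variance explained.
    Includes the conventional moving-bar receptive field estimator, MUA
    envelope and multitaper LFP band-power derivation from raw signals,
    population-level eccentricity-size statistics, and synthetic data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    minpack.lm,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
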