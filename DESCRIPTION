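Package: somadose
Title: Dose-Exposure-IGF-I Response Modelling and Simulation for
    Once-Weekly Somapacitan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic/pharmacodynamic modelling and
    virtual-trial simulation of growth hormone replacement therapy in adult
    growth hormone deficiency, for once-weekly somapacitan and once-daily
    somatropin.  Provides structural turnover (indirect-response) models of
    the IGF-I response, an age- and sex-specific IGF-I standard deviation
    score transform, multiplicative covariate and log-normal variability
    models, Laplace-approximation nonlinear mixed-effects estimation from
    sparse event-record data, calibration of a reference parameter set to
    published group-level dose-response anchors, simulation of clinical
    dose-titration algorithms, missed-dose (forgiveness) analyses, and a
    synthetic virtual-trial generator with NONMEM-style dataset input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
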