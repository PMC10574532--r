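Package: dgim
Title: Gastrointestinal Transfer Dissolution Simulation and Level-A IVIVC
Version: 0.1.0
Authors@R:
    person("DGIM", "Maintainers", email = "dgim@example.org", role = c("aut", "cre"))
Description: Simulates the multi-cup dynamic gastrointestinal model (DGIM): a
    stomach-duodenum-jejunum transfer dissolution apparatus with first-order
    gastric emptying, biorelevant secretion and n-octanol absorptive phases,
    for weakly basic drugs that supersaturate and precipitate on the gastric
    to intestinal pH shift. Includes a single-vessel USP apparatus II pH-shift
    biphasic test, pH-dependent solubility modelling via a modified
    Henderson-Hasselbalch equation, degree-of-supersaturation metrics, single
    and double Weibull dissolution models with AIC selection, non-compartmental
    pharmacokinetics, and a complete Level-A in vitro-in vivo correlation
    engine: polyexponential unit-impulse-response fitting, non-negative
    staircase deconvolution, time-scaled correlation fitting, convolution
    prediction and FDA-style prediction-error validation.
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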