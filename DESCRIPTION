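Package: doserl
Title: Reinforcement-Learning Adaptive Allocation for Dose-Response Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and design toolkit for block-sequential phase II
    dose-response trials analysed with MCP-Mod. Provides the dose-response
    scenario generator (linear, Emax, sigmoid Emax, quadratic, exponential
    and flat families calibrated to a stated maximum effect), the full
    MCP-Mod analysis chain (optimal contrasts, max-T multiple contrast test,
    candidate model fitting, AIC selection, continuous minimum-effective-dose
    estimation), model-averaged D- and TD-optimal designs with
    Pukelsheim-Rieder efficient rounding and adaptive blockwise variants, a
    trial Markov decision process, a proximal-policy-optimization trainer
    that learns adaptive allocation rules directly optimizing power, model
    selection, target-dose accuracy or mean absolute error, and an
    evaluation harness with type-I-error recalibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    withr,
    optparse
Config/testthat/edition: 3
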