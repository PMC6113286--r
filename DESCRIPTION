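Package: revkernel
Title: Psychophysical Reverse Correlation for Bounded Evidence-Accumulation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and estimators for studying how decision-making mechanisms
    shape psychophysical reverse correlation. Provides frame-based simulators for
    bounded and unbounded drift-diffusion decisions (with non-decision time,
    collapsing-bound urgency, and starting-point bias) and for two competing
    accumulators with input correlation, leak, mutual inhibition, and a reflective
    lower bound; stimulus- and response-aligned psychophysical kernel estimation with
    the analytic normalizations that make kernels directly comparable to the
    generating sensory weights; a Fokker-Planck first-passage solver and
    maximum-likelihood fitting of drift-diffusion parameters to choice and
    reaction-time data, including kernel prediction from fitted parameters; and
    opponent motion-energy filtering of random-dot kinematograms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
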