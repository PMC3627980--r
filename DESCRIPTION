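Package: phaseloop
Title: Closed-Loop Optogenetic Phase Control of Gamma-Oscillating Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workbench for precisely timed closed-loop optogenetic
    stimulation of gamma-oscillating neuronal populations. Implements a
    phenomenological, intensity-dependent model of channelrhodopsin-2 (ChR2)
    photocurrents, a conductance-based spiking network simulator of one or two
    partially transduced Wang-Buzsaki populations with frozen-noise perturbation
    pairs, Hilbert- and linear-phase analysis of LFP-like signals, empirical
    phase-response-curve estimation, analysis of multistable inter-areal phase
    locking (induced shifting and switching), an online phase-prediction
    pipeline (testing, monitoring, AR(1)/linear onset forecasting) and a
    surrogate generator of oscillations with autoregressive cycle-to-cycle
    period fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    minpack.lm,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
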