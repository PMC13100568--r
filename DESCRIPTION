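Package: oculoscope
Title: Generative Simulation and Joint Analysis of EEG and Eye-Tracking Recordings
Version: 0.1.0
Authors@R:
    person("Oculoscope", "Developers", email = "oculoscope@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how oculomotor action shapes scalp EEG
    phenomena. Provides a generative simulator in which a stereotyped
    biphasic potential preceding each saccade and regularly recurring
    fixation-control events, superposed on 1/f background noise, give rise
    to event-related potentials, sustained late positivities and alpha-band
    power without any imposed oscillatory source; synthetic session
    generation with gaze traces and plain-text I/O; gaze metrics (velocity,
    density maps, dispersion, saccade detection); an ERP pipeline with
    saccade-latency binning and saccade-locked re-alignment; a Hanning-taper
    time-frequency pipeline with dB baselining and simplified aperiodic
    removal; and the matching statistics: cluster-based permutation tests,
    distribution stratification, circular-shift surrogate correlations,
    trial-level mixed models and 2x2 repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
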