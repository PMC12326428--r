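Package: playbacklogger
Title: Simulation and Analysis of Autonomous Audio-Playback Bio-Loggers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for autonomous
    audio-playback experiments on animal-borne bio-loggers. Generates
    seeded multimodal sensor streams (25 Hz tri-axial acceleration, 1 Hz
    GPS, 30 FPS video mask-pixel ratios) with ground-truth behaviour
    labels, trains and evaluates a compact on-board-style decision-tree
    behaviour classifier, drives a tick-synchronous playback controller
    with geofencing, GPS fix-quality gating and refractory lockout, and
    analyses behavioural responses via smoothed vectorial dynamic body
    acceleration (S-VeDBA), ground-speed differences (AD-Speed) and
    masked-pixel-ratio differences (AD-MPR), a Bayesian hierarchical
    random-intercept pre/post model with a self-contained MCMC sampler,
    and a local-level Bayesian structural time-series counterfactual.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    rpart,
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
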