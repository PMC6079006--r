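Package: freqtag
Title: Frequency-Tagged MEG Analysis of Auditory Statistical Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for frequency-tagged
    magnetoencephalographic (MEG) studies of auditory statistical learning.
    Generates statistically structured tone streams (tritone-segmented,
    random, and habituation scales) on the 5.505 Hz / 1.835 Hz tagging grid,
    simulates 306-channel MEG-like recordings with phase-locked periodic
    responses and 1/f background noise, and recovers tagged responses via
    neighbour-bin signal-to-noise spectra, cluster-based permutation tests
    over sensor topographies, AICc-based linear mixed-model selection of
    temporal dynamics, and two-alternative forced-choice behavioural
    analyses with JZS Bayes factors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
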