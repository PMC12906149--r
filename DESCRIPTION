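Package: softafc
Title: Softmax Decision Models for 3AFC Auditory Detection Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-alternative forced-choice (3AFC) auditory
    detection experiments for normal-hearing and electric-hearing (cochlear
    implant) frontend profiles. Stimuli for masker-probe and
    amplitude-modulation detection paradigms are converted into
    tonotopically organised single-fiber spike trains by a stochastic
    surrogate auditory-nerve frontend (or any user-supplied frontend
    honouring the same contract), binned into band-by-time internal
    representations, passed through a forward-masking stage, perturbed by
    relative internal noise, and correlated per critical band with an
    auditory-memory template. A temperature-parameterised softmax (or a
    legacy winner-take-all rule) converts per-band correlations into choice
    probabilities, yielding psychometric curves whose slope is controlled
    by the temperature and whose position is controlled by the noise level.
    Includes YAML-configured experiment drivers, CSV/JSON curve
    serialisation, logistic curve fitting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    signal,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
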