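Package: behaviorome
Title: Lifelong Behavioral Aging Analysis from Keypoint Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying behavioral aging in continuously tracked
    animals. Converts 2-D body-keypoint tracks into per-frame pose features,
    segments behavior into Gaussian hidden-Markov-model syllables fitted by
    memory-bounded stochastic EM, summarizes daily behavior as a syllable by
    time-of-day by animal-day usage tensor factorized by non-negative
    canonical polyadic decomposition, builds behavioral clocks of age and
    age-fixed lifespan classifiers from the resulting age factors, and
    detects discrete life stages via usage divergence, kernel change-point
    detection, and a life-stage hidden Markov model. Includes a synthetic
    cohort generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
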