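Package: voxpath
Title: Speech and Singing Vocal Parameters, Attractiveness Ratings, and
    Path-Model Inference
Version: 0.1.0
Authors@R:
    person("Voxpath", "Maintainers", email = "voxpath@example.org",
           role = c("aut", "cre"))
Description: Tools for the bioacoustic analysis of paired speech and singing
    recordings and their perceptual ratings. Converts fundamental frequency
    to the semitone scale, estimates formant spacing and apparent vocal
    tract length from the first four formants of a uniform-tube model,
    aggregates rater-by-target attractiveness matrices with Cronbach's
    alpha reliability, and fits a recursive observed-variable path model
    linking body measures, vocal parameters, attractiveness, and
    sociosexuality.  Inference for the path model uses permutation-null
    p-values, leave-one-out (jackknife) stability certification, and
    multi-group path-invariance chi-square difference tests.  A calibrated
    synthetic-cohort generator reproduces the distributional structure the
    analyses assume, so the full pipeline is testable without access to
    raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
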