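Package: hebbrsa
Title: Representational Similarity Analysis for Hebb-Repetition Tone-Sequence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing Hebb-repetition
    working-memory experiments with supra-span tone sequences. Generates
    constrained match/mismatch sequence-recognition designs, computes
    Earth-Mover's-Distance model dissimilarity matrices over tone sequences,
    estimates single-trial multivoxel activity patterns with a partial
    least squares beta-series procedure, computes representational
    similarity effects for repeated versus novel sequences together with
    per-run learning trajectories, groups regions of interest by a
    univariate encoding/delay conjunction with false-discovery-rate
    control, and fits group-level mixed-effects models. Includes a
    synthetic BOLD generator that emulates the statistical structure the
    analysis assumes, including repetition-driven pattern stabilization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
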