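Package: mfaim
Title: Multifractal Nonlinearity Analysis of Aiming Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nonlinear interactions across time scales
    in rhythmic aiming movement. Implements direct (Chhabra-Jensen)
    multifractal spectrum estimation, iterative amplitude-adjusted Fourier
    transform (IAAFT) surrogate testing, and the standardized surrogate
    t-statistic of multifractal nonlinearity, together with kinematic
    preprocessing of motion-capture recordings from a two-target tapping
    (Fitts) task: lateral hand projection, head interpoint-distance series,
    contact detection, cycle-based epoching, and per-epoch aiming
    variability SD(Aim). A mixed-effects interaction model relates aiming
    variability to the multifractal covariates, with bootstrap power
    analysis and effect-range summaries. A synthetic-data generator
    (binomial cascades, linear-Gaussian nulls, and full simulated task
    sessions with planted effects) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
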