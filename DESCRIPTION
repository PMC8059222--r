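Package: owlmove
Title: Behaviour-Specific Habitat Selection for GPS-Tracked Farmland Raptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse high-frequency GPS tracks of central-place
    foraging raptors (motivated by breeding barn owls in farmland) by
    behavioural mode.  Provides a synthetic landscape-and-track generator
    with known ground truth, position filtering and step kinematics,
    expectation-maximization binary clustering of steps into perching,
    hunting and commuting, kernel home-range estimation with a simplified
    autocorrelation adjustment, Manly third-order selection ratios for
    roosting and perching, integrated step-selection functions with
    empirical-distribution alternative steps fitted by conditional
    logistic regression, path-selection functions for commuting flights
    with relocate-and-rotate null paths, commuting straightness metrics,
    and non-metric multidimensional scaling of per-individual selection
    coefficients with permutation-based environmental fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    vegan,
    withr
Config/testthat/edition: 3
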