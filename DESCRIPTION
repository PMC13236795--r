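Package: stepinit
Title: Simulation and Analysis of Anticipatory Postural Adjustments in
    Forward Single-Step Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for go/no-go forward single-step
    initiation experiments on a force platform. Builds the experimental
    trial schedules, generates mechanically self-consistent synthetic
    force-plate recordings from a crossed mixed-effects generative model,
    reduces raw anteroposterior force, vertical force and mediolateral
    moment channels to centre-of-pressure and centre-of-mass kinematics
    (zero-lag fourth-order Butterworth filtering, Newton's-law
    acceleration, trapezoidal integration), detects anticipatory postural
    adjustment events and the six spatiotemporal outcome variables,
    applies the four go-trial rejection rules, and fits crossed
    random-intercept linear mixed models with Satterthwaite degrees of
    freedom, estimated marginal means, Tukey-adjusted contrasts,
    semi-partial R-squared effect sizes, and a simulation-based power
    procedure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
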