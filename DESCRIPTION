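Package: postcoord
Title: Self-Organizing Hip-Ankle Postural Coordination via Deep Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planar hip-ankle standing-humanoid simulator with a head-tracking
    task, a proximal policy optimization (PPO) learner written in base R, and a
    coordination-analysis layer (hip-ankle correlation, cycle-based relative
    phase, center-of-pressure statistics, energy cost) for studying the
    self-organized alternation between in-phase and anti-phase postural
    coordination modes as target frequency, energy penalty, hip stiffness and
    upper-body mass change. Includes configuration-driven experiment sweeps and
    a synthetic joint-angle fixture generator so the analysis layer is testable
    without any training run.
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
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
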