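Package: graspquality
Title: Grasp Optimality Scoring, Stimulus Design, and Simulated Grasp-Quality Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models two-digit precision-grip grasp selection on polycube objects
    made of wood and brass. Builds rigid polycube stimuli with mass and center of
    mass, enumerates candidate thumb-index grasps on the exposed surface, scores
    them under four optimality criteria (grasp aperture, alignment with the
    natural grasp axis, gravitational torque about the grasp axis, and object
    occlusion) subject to a two-contact force-closure constraint, and selects
    criterion-isolating pairs of near-optimal and sub-optimal grasps. A parametric
    two-alternative forced-choice observer simulates per-trial "which grasp is
    better" judgments across vision, video, and grasping sessions, and the
    analysis layer provides percent-correct summaries, t-tests against chance,
    bootstrapped confidence intervals, BEST-style Bayesian estimation with highest
    density intervals and regions of practical equivalence, effect sizes,
    replication-subset selection, and within-session learning-trend checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
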