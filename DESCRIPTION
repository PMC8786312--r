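Package: fishnum
Title: Controlled Numerosity Stimuli and Choice Analysis for Fish Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-alternative forced-choice numerosity discrimination
    experiments with fish. Generates pairs of dot-array stimuli that differ in
    numerosity while equating non-numerical magnitudes (total area, total
    perimeter, element radius, convex hull, inter-distance) under six crossed
    control conditions; quantifies array magnitudes and codes the congruency
    between each magnitude and numerosity; summarises stimulus spatial-frequency
    content by radially averaged Fourier amplitude ("total power"); builds
    training sessions, probe-test blocks and the learning-criterion logic of a
    daily-session operant protocol; and analyses choice data with exact binomial
    tests, Cohen's g, random-intercept binomial mixed models with backward model
    selection, and Tukey-adjusted contrasts. A synthetic-data module simulates
    per-fish Bernoulli choice tables with session structure so the whole
    pipeline can be exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    utils,
    lme4,
    emmeans,
    jsonlite,
    png,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
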