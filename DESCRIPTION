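Package: kineticsm
Title: Statistical Principal-Mode Models of Hip and Knee Joint Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates statistical models of inter-subject variability in
    hip and knee joint-reaction-force waveforms recorded during deep squatting and
    forward lunging. Raw trials are trimmed on knee flexion, aligned so that peak
    knee flexion sits at 50% motion progress, and resampled to 101 instants; the
    six body-weight-normalized force channels are stacked into 606-element feature
    vectors and decomposed by correlation-matrix principal component analysis.
    The fitted model supports truncated reconstruction, virtual-subject sampling,
    and the standard statistical-model goodness measures (accuracy, compactness,
    generalization, specificity) together with Monte-Carlo permutation selection of
    signal components (rank-of-roots and equality-of-roots criteria). A synthetic
    cohort generator with planted low-rank structure supports end-to-end testing
    and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
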