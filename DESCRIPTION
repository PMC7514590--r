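Package: gazeMEM
Title: Multilevel Entropy Maps for Eye-Movement Event Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects eye-movement events (the saccadic period within
    jumping-point gaze recordings) from the regularity structure of the
    velocity signal.  Approximate entropy (ApEn) is computed on a dyadic
    multiresolution time-scale grid, yielding a Multilevel Entropy Map
    (MEM) per stimulus trial; cross-level feature vectors assembled from
    the map are classified with a deterministic k-nearest-neighbour
    classifier under leave-one-participant-session-out cross-validation.
    Includes gaze CSV input with two-point differentiation to velocity,
    map averaging and rendering, segment-wise ANOVA/Tukey comparison,
    and a seeded synthetic jumping-point simulator with ground-truth
    saccade windows for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, pracma, class, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'entropy.R'
    'io.R'
    'mem.R'
    'features.R'
    'classify.R'
    'segstats.R'
    'synth.R'
    'show-methods.R'
    'gazeMEM-package.R'
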