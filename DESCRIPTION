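Package: itwgait
Title: Ankle Kinematics in Idiopathic Toe Walking Across Mono- and
    Multi-Segment Foot Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sagittal ankle kinematics from 3D marker trajectories
    under three foot models - the multi-segment Oxford hindfoot model (OFM)
    and the mono-segment Plug-in-Gait (PiG) and Davis (DAV) models - and
    evaluates how the choice of model changes the clinical characterization
    of idiopathic toe walking. Includes zero-lag Butterworth filtering of
    marker data, gait-event detection from vertical ground reaction force,
    time normalization of gait cycles, representative-cycle selection by
    median-waveform distance, linear-fit-method consistency, extraction of
    clinical ankle parameters, rule-based heel/forefoot rocker
    classification, a 3 x 2 repeated-measures factorial analysis with an
    aligned-rank-transform fallback and Bonferroni post-hocs, and a
    forward-kinematics synthetic gait generator with known ground-truth
    joint angles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
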