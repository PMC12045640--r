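Package: wavegait
Title: Gait Kinematics, Spectral Coherence and Path Analysis for Larval
    Hexapod Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the locomotion of six-legged insect
    larvae from video point-tracking output. Reads leg-tip and body-centroid
    trajectory tables, segments leg velocity traces into swing and stance
    phases, and computes cycle periods, duty cycles, stride lengths and intra-
    and intersegmental phase relationships of the bilaterally symmetric
    posterior-to-anterior wave gait. Includes multitaper spectral coherence
    against an anchor leg with an analytic significance threshold, extraction
    of T3-to-T1 walk cycles with pause filtering, alignment of abdominal
    (pygopod) planting events to leg-swing initiations with Freedman-Diaconis
    binning and event-triggered velocity averages, and whole-animal path
    metrics (tortuosity, behavioural-state classification, headsweep bias,
    backtrack-and-redirect detection). A seeded synthetic gait and path
    generator provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
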