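Package: atf3net
Title: Deterministic Models of the Atf3-Egr1 Immediate-Early-Gene
    Negative-Feedback Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the Atf3-Egr1
    immediate-early-gene system in cardiomyocytes stimulated with
    endothelin-1: a base ERK1/2-driven transcription model and mechanistic
    extensions for Atf3 autorepression, RSK-driven repressor
    phosphorylation, de novo synthesis of an inhibitory transcription
    factor, and miRNA-mediated sequestration and decay of Atf3 mRNA.
    Includes a stiff ODE simulation engine with derived observables,
    profile feature extraction (peak times, percent declines,
    return-to-basal times), feature-based least-squares calibration of the
    signalling sub-models, one-at-a-time local parameter sensitivity
    scans, and a generator of experimental-style replicate time-course
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
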