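Package: erlangcycle
Title: Erlang Models and Coupling Statistics for Single-Cell Cell-Cycle
    Phase Durations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing single-cell time-lapse measurements of
    cell-cycle phase durations (G1, S, G2, M). Fits per-phase Erlang
    (integer-shape gamma) duration models by exact maximum likelihood,
    including a shared-rate Markovian variant and a Welch-Satterthwaite
    Erlang approximation to hypoexponential sums; computes pairwise
    phase-coupling statistics under a significance-and-effect-size policy
    with a measurement-noise-injection bootstrap and Fisher-z sample-size
    calculations; simulates the "many-for-all" heritable-factor model in
    which many weak phase-coupling factors leave phase durations
    simultaneously heritable and uncoupled; and generates synthetic phase
    tables, sister-cell lineages, and 1-D reporter traces with matching
    phase-boundary detectors for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
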