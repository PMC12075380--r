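Package: tgcwm
Title: Theta-Gamma Coupling Analysis for Visual Working-Memory EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing theta-gamma cross-frequency
    coupling in EEG recorded during a visual change-detection working-memory
    task. Provides a synthetic-data generator with known ground-truth
    phase-amplitude coupling, artifact-segment and amplitude-based epoch
    rejection, zero-phase band-pass and notch filtering, FFT band power over
    canonical frequency bands and electrode regions, the Tort modulation
    index and n:m phase-phase coupling, Cowan's K and reaction-time
    behavioural summaries, and group/paired/correlation statistics with
    Benjamini-Hochberg false-discovery-rate control. Reads and writes
    BrainVision and EDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
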