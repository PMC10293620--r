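Package: blastdose
Title: Blast-Wave Dosimetry, Behavior and Histology Quantification for
    Closed-Body Blast Injury Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for shock-tube (Advanced Blast Simulator)
    injury models: Friedlander waveform modeling and fitting, normal-shock
    reflected-overpressure calculation, pressure-trace conditioning
    (baseline correction, clipping detection and repair), per-pulse wave
    characterization and cross-shot repeatability summaries, open-field-test
    trajectory metrics, fluorescence immunohistochemistry quantification
    (area fraction, cell count, integrated density, area per cell), and
    two-group statistics.  Seeded synthetic-data generators emulate the
    sensor, behavior and microscopy data streams with known ground truth so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    minpack.lm,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
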