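Package: pcgseg
Title: ECG-Referenced Segmentation and Component Timing of Heart Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the two main heart sounds (S1, S2) on a phonocardiogram
    recorded simultaneously with a single-lead ECG, splits each sound into its
    two valve components (mitral/tricuspid for S1, aortic/pulmonary for S2),
    and measures the six R-peak-referenced timing parameters at 1-ms
    resolution. The pipeline band-passes the ECG with a linear-phase FIR
    cascade, detects R-peaks with a Pan-Tompkins style chain, band-passes the
    PCG (20-100 Hz, zero-phase Chebyshev), computes a second-order
    Shannon-energy envelope with moving normalization, and applies rule-based
    amplitude/time thresholding to detect, prune and classify heart-sound
    segments. Includes a synthetic paired ECG/PCG generator with exact ground
    truth for validation, per-beat timing summaries, an ensemble-average SNR
    estimate, sensitivity/specificity scoring, CSV/WFDB-style text I/O and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
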