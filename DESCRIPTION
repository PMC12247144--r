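Package: dryclean
Title: Artifact Reduction and Spatial Harmonic De-Noising for Dry EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cleaning pipeline for multichannel dry-electrode EEG recordings.
    Combines ICA-based physiological artifact removal (blinks, eye movements,
    myogenic, cardiac and pulse interference), spatial harmonic analysis
    (SPHARA) low-pass filtering on a finite-element discretization of the
    Laplace-Beltrami operator over the triangulated sensor montage, and
    zeroing of transient high-amplitude single-channel jump periods (AP0)
    before spatial filtering to prevent spatial smearing. Includes a seeded
    synthetic dry-EEG generator with ground-truth artifact annotations,
    signal-quality metrics (SD, SNR, RMSD), method-chain orchestration, and
    readers and writers for BrainVision and EDF recordings, electrode
    montages and artifact annotation files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    deldir,
    ica,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
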