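Package: rrmlilt
Title: Resonant Recognition Model Wavelength Prediction and Low-Intensity
    Light Cytotoxicity Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Resonant Recognition Model (RRM) analysis chain
    for low-intensity light therapy studies: electron-ion interaction
    potential (EIIP) encoding of protein sequences, amplitude and consensus
    (cross-spectral) spectra, characteristic-frequency detection with
    signal-to-noise scoring, conversion of characteristic frequencies to
    irradiation wavelengths (lambda = 201/f), LED panel selection and
    photometric bookkeeping, and quantitative analysis of LDH cytotoxicity
    and PrestoBlue viability plate assays across exposure regimes with
    one-way ANOVA. A synthetic-data module generates protein groups with a
    planted spectral component and simulated plate-reader datasets with the
    study's factorial structure, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
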