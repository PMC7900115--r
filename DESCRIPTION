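Package: irmix
Title: Spectral Deconvolution of Isomeric Glycolipid Mixtures from
    Cryogenic Infrared Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and relatively quantify isomeric glycolipids
    from gas-phase infrared fingerprint spectra. Provides a synthetic
    fingerprint generator (Gaussian band models, stick-spectrum broadening,
    linear molar mixing with additive noise), the binning and area
    normalization conventions used for infrared mixture analysis,
    ratio-weighted spectral averaging, a from-scratch non-negative matrix
    factorization (NMF) with multiplicative updates and reference-anchored
    component assignment, non-negative least-squares cross-validation,
    scripted accuracy and detection-limit studies, and small ion-chemistry
    helpers (monoisotopic mass, adduct m/z, Mason-Schamp collision cross
    sections).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
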