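Package: dporTrace
Title: Spectral Unmixing and Progress-Curve Kinetics for Dark-Operative
    Protochlorophyllide Oxidoreductase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes time-resolved UV-vis absorbance spectra of
    dark-operative protochlorophyllide oxidoreductase (DPOR) assays into
    free substrate (Pchlide), enzyme-substrate complex and product
    (Chlide) concentrations by least-squares fitting of calibrated
    reference spectra, and extracts rate constants for enzyme-substrate
    complex formation and electron-transfer-driven product formation
    with plateau one-phase and two-phase association models. Includes a
    deterministic simulator of the E+S<->ES->E+P kinetic scheme, a
    seeded synthetic-experiment generator with Gaussian band shapes and
    instrument noise, endpoint (acetone-quench) activity calculations,
    and a pipeline tying the stages together.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'assay.R'
    'spectrum-methods.R'
    'references.R'
    'unmix.R'
    'io.R'
    'kinfit.R'
    'mechsim.R'
    'synth.R'
    'pipeline.R'
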