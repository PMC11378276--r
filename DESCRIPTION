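Package: naquant
Title: Multivariate Quantification of Naphthenic Acids from
    Direct-Infusion ESI(-) Mass Spectra
Version: 0.1.0
Authors@R: person("naquant", "developers", role = c("aut", "cre"),
    email = "naquant@example.org")
Description: Quantifies total naphthenic acids in produced water from
    direct-infusion electrospray ionization (negative mode) high-resolution
    mass spectra. Provides peak-list CSV and centroided mzML import,
    fixed-width m/z binning and spectral alignment, row normalization and
    calibration-fitted column scaling, PLS1 (NIPALS) regression with
    Monte-Carlo leave-n-out cross-validation, ordered predictor selection
    (OPS) of m/z variables, dilution-corrected prediction reports against a
    reference method, CHO molecular-formula assignment with oxygen-class and
    double-bond-equivalent summaries, and a fully seeded synthetic spectrum
    generator so the whole calibration pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
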