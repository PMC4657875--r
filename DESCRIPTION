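Package: commrobust
Title: Functional Robustness of Exoenzyme Production in Model Bacterial
    Communities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the functional robustness of secreted
    enzyme activity (short- and long-chain lipases, choline-specific
    phospholipase C, proteases) in small synthetic bacterial communities
    under a leave-one-out dropout design. Provides a synthetic-data
    generator for a nine-member drinking-water isolate community
    (endpoint compositions, plate-reader assay signals, selective-plating
    colony counts), conversion of colorimetric and fluorometric signals
    to normalized activity units, differential-plating deconvolution of
    community composition, diversity and evenness indices, an
    expected-versus-observed community activity null model, and
    many-to-one (Dunnett) and Sidak-adjusted statistics for classifying
    per-enzyme robustness to single-species absence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
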