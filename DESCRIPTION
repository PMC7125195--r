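Package: kipik
Title: Kinase Identification from Inhibitor Fingerprint Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies the kinase responsible for a phosphorylation event
    from a plate-based inhibitor screen. Raw well absorbances are converted
    into a per-inhibitor standard-score and percent-inhibition fingerprint,
    which is correlated (Pearson) against reference kinase-inhibitor
    profiling matrices to rank candidate kinases. Confidence is quantified
    by permutation-null z-scores and by downsampling recovery curves, and
    kinases are clustered by inhibition fingerprint (1 - correlation
    distance, Ward.D2) with bootstrap clade support. A synthetic-screen
    simulator generates profiling matrices and ELISA-style plates so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
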