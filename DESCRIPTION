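Package: advesig
Title: Adverse Drug Reaction Signal Detection and Tumor Immune-Infiltrate
    Grade Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Disproportionality analysis of spontaneous adverse-drug-reaction
    line listings with the Proportional Reporting Ratio (PRR), the classical
    three-part signal rule (PRR >= 2, at least three cases, chi-square >= 4)
    and reaction-share summaries, together with tools for quantifying
    tumor-infiltrating immune cells (CD68 macrophages, CD20 B lymphocytes)
    across histological grades of canine mammary carcinoma: frequency tables,
    per-field infiltrate densities, two-sample tests computed from summary
    statistics, and serum neutrophil-lymphocyte and platelet-lymphocyte
    ratios. Seeded synthetic-data generators for both data kinds, with known
    injected signals, support offline validation of the whole pipeline,
    including Monte-Carlo estimation of the signal rule's false-positive rate
    and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
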