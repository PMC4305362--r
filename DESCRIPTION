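Package: twowaytables
Title: Publication-Ready Tables for Two-Way ANOVA with Post-Hoc Letter Displays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Turns long-format two-factor experimental data into
    publication-ready statistical tables. Fits the two-way analysis of
    variance with interaction (sequential sums of squares), performs
    all-pairwise comparisons of treatment means under the cell-means model
    (Fisher LSD with optional Bonferroni/Holm adjustment, Tukey-Kramer,
    Student-Newman-Keuls, Duncan, and a resampling step-down max-t
    procedure), encodes the significance pattern as a compact letter
    display, summarises cells as mean +/- SEM or as means with a pooled
    SEM, and exports the assembled tables as RTF documents with
    auto-generated captions. Interaction plots can be written to PDF, and
    a synthetic-data generator produces two-factor normal datasets with
    known ground truth. Reads single- and multi-sheet Excel workbooks and
    CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    readxl,
    rlang,
    readr,
    tibble,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
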