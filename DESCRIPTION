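Package: cogwheel
Title: Edwards 'Cogwheel' Venn Analysis of Two to Six Named Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions two to six named sets of string identifiers (protein
    symbols, GO term names, pathway names, or arbitrary labels) into their
    complete disjoint intersection regions, classifies every region against a
    reference (non-stimulated) set with a five-colour scheme, and draws valid
    Edwards "cogwheel" Venn diagrams whose geometry is verified by grid
    sampling rather than assumed. Includes spreadsheet input/output
    (CSV/TSV/XLSX, one column per set), per-region membership exports,
    dose-response summaries (dose-unique counts and proportions,
    cross-context overlap), a synthetic fixture generator with known ground
    truth, and a small command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    grDevices,
    xml2
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    png,
    jsonlite
Config/testthat/edition: 3
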