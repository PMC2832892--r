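Package: snoscout
Title: Annotation, Structure, Target and Retrogene Analysis of Intermediate-Size ncRNA Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intermediate-size non-coding RNA (ncRNA)
    catalogs built from cDNA libraries, with a focus on small nucleolar RNAs
    (snoRNAs). Provides priority-ordered library annotation from alignment hit
    tables, C/D and H/ACA box-motif detection with maximum-base-pairing
    secondary structure, 2'-O-methylation and pseudouridylation target
    prediction, cross-genome conservation scoring, six-group cross-species
    expression classification, snoRNA family and paralog censuses, SINE-like
    retrogene feature detection (poly(A) tails, target site duplications,
    L1 endonuclease sites, shared flank consensus blocks), and a synthetic
    genome generator with a machine-readable truth ledger for planted-element
    recovery testing. Ships a 117-entry rhesus monkey ncRNA catalog fixture
    with northern-blot expression calls and conservation scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    stringi,
    readr,
    rlang,
    withr,
    ggplot2,
    Rcpp,
    ape,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
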