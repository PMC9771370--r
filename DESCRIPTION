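Package: switchjunc
Title: Switch-Junction Breakpoint Calling and Classification for Class
    Switch Recombination Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing immunoglobulin class switch recombination
    (CSR) junction sequencing reads of the LAM-HTGTS style. Builds a dual
    strain-background (C57BL/6 / S129) consensus reference for the donor
    (bait, S-mu) and acceptor (prey, S-gamma-1) switch regions, decomposes
    each read into a bait segment, junction and prey segment, measures
    microhomology, insertions, flank deletions and point mutations with
    strain variants masked, filters non-recombined germline products, and
    aggregates per-read calls into genotype-level class frequencies,
    insertion-length histograms, mutation spectra and the associated
    Student's t and chi-square goodness-of-fit statistics. A synthetic
    junction-read generator with exact per-read ground truth makes every
    stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
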