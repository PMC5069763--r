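Package: kmerpalette
Title: Strain-Aware Metagenomic Profiling from Common k-mer Palettes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles shotgun metagenomic samples against a reference genome
    database using exact k-mer containment ("common k-mer") matrices at two
    k-mer sizes. Novel, unsequenced organisms are modelled by
    similarity-capped hypothetical columns whose two k-mer sizes are linked
    by a fitted cubic polynomial; relative abundances are recovered with a
    sparsity-promoting nonnegative least-squares deconvolution. Outputs
    rank-wise taxonomic profiles in the Bioboxes profiling format and
    strain-level neighbor-joining trees with placed hypothetical mass.
    Includes a deterministic synthetic community simulator so the whole
    pipeline is testable without reference downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    pracma,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
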