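Package: intronscout
Title: Survey of Group II Intron Copies, Homing Sites and Occupancy in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects group II intron copies in bacterial genomes against a
    reference intron library using a seed-and-extend local alignment search
    with two-round detection, classifies copies as full-length or fragments,
    resolves orthology between strains from 3 kb flanking sequences, infers
    potential retrohoming target ("homing") sites by four schemes (flank
    similarity, EBS/IBS base-pairing consensus, Rho-independent terminator
    gating for class C introns, and flank conservation consensus), and
    computes homing-site occupancy statistics used to contrast
    selection-driven versus saturation-driven extinction dynamics of these
    retroelements. Includes a synthetic genome generator with full ground
    truth so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
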