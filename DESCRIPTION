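Package: satmapper
Title: Satellitome Characterization and In Silico Chromosome Mapping of
    Satellite DNA Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes the satellitome of a genome from a library of
    satellite DNA (satDNA) consensus monomers. Annotates monomers on
    chromosome-scale assemblies with a semi-global similarity scan at a
    configurable identity threshold, merges monomer hits into tandem
    arrays, and serializes annotations to GFF3/BED. Estimates per-family
    genome abundance and Kimura two-parameter (K2P) divergence from
    sequencing reads masked against dimer/concatemer search libraries,
    and draws repeat landscapes and per-chromosome satDNA distribution
    maps. Includes a synthetic-data generator that plants tandem arrays
    mutated to a target K2P divergence so every step can be validated
    against known truth.
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
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    Rcpp,
    methods,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
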