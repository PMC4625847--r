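Package: mlstkit
Title: Multilocus Sequence Typing and Clonal Population Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multilocus sequence typing (MLST) of bacterial
    isolates: allele cataloguing and sequence-type assignment from
    housekeeping-gene fragments, clonal-complex inference from single-locus
    variant sharing with founder prediction, minimum spanning trees over
    allelic profiles, per-locus diversity statistics (polymorphic sites,
    nucleotide diversity, synonymous and nonsynonymous site classification,
    Nei-Gojobori dN/dS), multilocus linkage disequilibrium (index of
    association and its standardized form with permutation tests),
    neighbour-joining phylogenies under the Kimura two-parameter model with
    bootstrap support, and split decomposition networks. Includes a seeded
    simulator of clonal bacterial populations with point mutation and
    whole-locus recombination for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
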