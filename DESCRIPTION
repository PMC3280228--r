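Package: aldhcensus
Title: Gene-Family Census, Nomenclature and Stress-Response Screening for
    the Grape ALDH Superfamily
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a genome-wide census of the aldehyde dehydrogenase
    (ALDH) gene superfamily in grapevine (Vitis vinifera) and beyond:
    PROSITE-style motif scanning and identity search for candidate
    discovery, family/subfamily assignment under the ALDH Gene Nomenclature
    Committee percent-identity rules (>40% family, >60% subfamily),
    neighbor-joining phylogenies with bootstrap support, exon-intron
    structure comparison and alternative-splice-event calling, tandem and
    segmental duplication detection with synteny-block ortholog mapping,
    cross-organism family accounting, and a microarray differential
    expression screen (quantile normalization, detection-call filtering,
    empirical-Bayes moderated t, Benjamini-Hochberg FDR). Packaged
    machine-readable transcriptions of the in-text gene and family tables
    plus a seeded synthetic-data generator make every stage testable
    without external downloads.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    limma,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
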