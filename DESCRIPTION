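Package: genomesurvey
Title: Genome Survey Statistics from Reads, Repeats, Annotations and Synteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Survey-level characterization of large, repeat-rich insect genomes
    from short-read data and standard annotation tables. Implements k-mer
    frequency-spectrum estimation of genome size, sequencing depth and
    repetitive fraction; a Phobos-style tandem-repeat scanner for micro- and
    minisatellites with affine mismatch penalties; decision rules for
    homology-based and de novo gene-set construction; summaries of nuclear
    mitochondrial insertions (NUMTs) and repeat-element content including a
    coverage-normalized read-based repeat fraction; mitogenome completeness and
    gene-order checks; and synteny haplotype-block construction from ortholog
    gene order. A synthetic-data module generates genomes, reads and annotation
    tables with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
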