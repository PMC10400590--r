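Package: dropmeth
Title: Droplet Single-Cell Bisulfite Sequencing: Simulation, Demultiplexing,
    Alignment, Methylation Calling and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for droplet-based single-cell whole-genome
    bisulfite sequencing experiments. Provides closed-form calculators for
    droplet-experiment design (Poisson cell loading, droplet counts and device
    runtimes, expected barcoded-cell yield), a synthetic-data generator (toy
    genomes with an unmethylated spike-in contig, cell-type methylomes with
    planted differentially methylated regions, droplet encapsulation and fusion
    with ground truth, paired-end bisulfite reads with an in-read cell barcode),
    barcode demultiplexing with error correction, a miniature three-letter
    bisulfite aligner, per-cytosine methylation calling into allc tables,
    mixture-model cell calling on mapping efficiency, species-purity
    classification, binned methylome clustering with DMR z-score annotation,
    and a pseudobulk two-group DMR caller. All user-facing functions take data
    frames and return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    data.table,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
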