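Package: bitsig
Title: Bit-Packed Binary Signature Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: All-vs-all similarity search over binary signatures (gene
    expression up/down calls, ortholog presence/absence, gene sets) using
    bit-packed 64-bit words and hardware population counts. Provides
    AND/XOR/OR pair counts for query-vs-library and self comparisons with
    memory-bounded chunked evaluation, threshold binarization of continuous
    matrices, exact cosine/Euclidean reference metrics with a
    filter-then-refine driver, signature connectivity networks with
    common-neighbor similarity and hypergeometric set-overlap enrichment,
    taxonomic shared-gene summaries for genome gene-content comparison, and
    synthetic generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
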