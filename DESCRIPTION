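Package: lhdriver
Title: Laplacian Heat Diffusion for Multi-Omics Driver Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate cancer driver genes on a weighted
    protein-protein interaction network by Laplacian heat diffusion
    H(t) = H(t0) exp(-Lt) from per-omics-level seed gene sets, followed by a
    three-stage statistical screen (permutation test on heat values, maximum
    association score against validated drivers, maximum function score from
    hypergeometric enrichment profiles) and pairwise intersection of the
    surviving latent gene lists across omics levels. Includes a STRING-style
    links-file reader, a GMT annotation reader, and a planted-module
    synthetic network generator for desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
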