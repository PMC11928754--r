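Package: panmum
Title: Anchor-Based Multiple Alignment of Highly Similar Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Colinear multiple alignment of sets of highly similar DNA
    sequences (e.g. the same chromosome assembled from many individuals of
    one species). Sequences are first compressed by prefix-free parsing;
    multiMUM anchors are found on the parse level with an enhanced
    generalized suffix array, chained into a backbone, extended across
    isolated mismatches on the base level, and the regions between anchors
    are closed recursively with partial multiMUMs, a built-in fragment
    mapper and a center-star aligner for small gaps. Includes alignment
    quality metrics (coverage, identity, sum-of-pairs value) and a
    synthetic pangenome simulator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
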