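Package: ktsketch
Title: Multi-Resolution k-mer Jaccard and Containment Estimation with
    Truncatable Sketches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates k-mer Jaccard and containment indices between
    sequence collections for many k-mer sizes simultaneously from a single
    reference database. Bottom-m sketches store the k-mers themselves (the
    elements attaining the smallest hash values, "argmin" sketches) rather
    than hash values, so a sketch built at one large k-mer size can be
    truncated to any smaller size by prefix lookup in a k-mer ternary
    search tree. Includes a streaming containment estimator over the tree
    with a bloom prefilter, classic fixed-k MinHash baselines, brute-force
    oracles with closed-form truncation-bias computations, seeded
    generators for synthetic microbial communities and shotgun reads, and
    a command-line interface with a plain-text database format.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
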