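Package: Qmodes
Title: Alignment of Replicate Mixed-Membership Clustering Results for
    Population Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns replicate membership (Q) matrices from unsupervised
    mixed-membership clustering programs such as Structure, ADMIXTURE and
    fastStructure. Resolves label switching between runs with the same
    number of clusters K by optimal one-to-one cluster matching, detects
    distinct solutions ("modes") by community detection on the pairwise
    alignment-similarity network, aligns modes across different values of
    K through anchor mode pairs with exact surjective many-to-one
    matching, and renders multipartite bar-plot graphs, alignment-pattern
    graphs and interleaved model-comparison figures. Includes a seeded
    synthetic-fixture generator with planted permutations, modes and
    cluster splits, and a modular pipeline whose steps exchange plain
    CSV/JSON/.Q artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
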