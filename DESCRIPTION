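Package: megrank
Title: Network-Weighted Detection of Monotonically Expressed Genes Across
    Tumor Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes whose expression changes monotonically across
    ordered cancer pathologic stages. Each sample's expression vector is
    re-weighted against a gene-interaction network by solving the GeneRank
    linear system (I - dWD^-1) r = (1 - d) e, after which genes are screened
    with Kruskal-Wallis tests, adjusted for multiple testing, and classified
    as monotonically increasing or decreasing from their stage-wise means.
    Also provides the unweighted Kruskal-Wallis baseline and an MFSelector
    comparator (total discriminating error with a label-permutation null),
    plus a planted-signal simulator of expression matrices, stage designs and
    interaction networks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
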