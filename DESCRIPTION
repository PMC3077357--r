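Package: spd
Title: Sample Progression Discovery from Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers a biological progression (possibly branched) underlying
    an unordered gene-expression matrix. Genes are grouped into coherent
    modules by iterative consensus k-means, a minimum spanning tree over the
    samples is built per module, modules whose gradual expression changes
    support a common progression are identified through a permutation-based
    concordance test, and an overall minimum spanning tree over the selected
    modules' genes is reconstructed as the progression hypothesis. Includes
    evaluation utilities (topological-overlap tree distance, random-tree
    nulls, bootstrap robustness), a hypergeometric gene-set enrichment helper,
    and a synthetic-data simulator with planted path and branched
    progressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
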