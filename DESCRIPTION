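Package: netcoal
Title: Trees Within Phylogenetic Networks Under the Multispecies Network Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for reasoning about the trees contained inside rooted
    phylogenetic networks when incomplete lineage sorting is at play.
    Reads networks in extended (rich) Newick with inheritance
    probabilities, enumerates displayed and parental trees via MUL-tree
    conversion, computes exact gene-tree topology probabilities under the
    multispecies network coalescent, detects anomalous gene trees and
    scans anomaly zones, simulates gene trees within a network by a
    backward-in-time coalescent, and recovers a network's parental trees
    from gene trees by clustering (Robinson-Foulds distances,
    multidimensional scaling, k-means with silhouette model selection,
    and per-cluster minimize-deep-coalescence inference scored by
    minimum-weight edge cover).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
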