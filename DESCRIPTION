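Package: profhom
Title: Profile-Based Remote Homology Detection for Divergent Paralogous
    Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies remote homology among deeply divergent
    paralogous protein families, such as the subunits of the CATCHR-class
    multisubunit tethering complexes (exocyst, COG, GARP, DSL1). Implements
    reciprocal profile-based orthology with multi-seed consensus, coiled-coil
    (heptad) prediction and masking, all-vs-all profile-profile local
    alignment with empirical shuffle-null significance, consensus cladograms
    from hierarchical clustering, and modularity clustering of thresholded
    similarity networks. A self-contained simulator generates protein
    families under a duplication-neofunctionalization model of an ancestral
    tetramer, with twilight-zone divergence and a shared N-terminal
    coiled-coil confounder, so the whole pipeline is testable without
    external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
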