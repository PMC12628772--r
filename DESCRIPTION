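Package: nitrilink
Title: Linking Microbial Community Diversity to Nitrification Performance
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for relating microbial biodiversity to nitrification
    performance in activated-sludge systems. Delineates the nitrifier guild
    and its association-filtered subcommunities from compositional amplicon
    count data using SparCC correlation networks swept across cutoffs,
    quantifies alpha diversity and Bray-Curtis/PCoA compositional dynamics of
    each community slice, and measures how much of the variation in the
    nitrification rate each slice explains via multiple linear regression,
    random-forest importance, and distance-based redundancy analysis with
    hierarchical partitioning. Includes k-mer/medoid re-clustering of amplicon
    sequence variants, repeated rarefaction, nitrification chemistry metrics,
    and a synthetic-community generator with planted association structure so
    the whole chain is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    withr
Config/testthat/edition: 3
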