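Package: karstbeta
Title: Beta-Diversity Partitioning and Null-Model Tests for Subterranean
    Communities of Karst Massifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse terrestrial subterranean (cave) communities
    sampled across the three-dimensional matrix of a karst massif.  Implements
    trap-effort normalization of abundance data, incidence-based Jaccard
    dissimilarity, pairwise analysis of similarities (ANOSIM), UPGMA
    clustering with Newick export, Mantel tests with Spearman correlation
    against 3D Euclidean distances, and additive partitioning of multiple-site
    beta diversity into species turnover and nestedness components.  Observed
    beta-diversity patterns are tested against fill-preserving null models in
    which the total number of presences in the massif is held constant while
    occurrences are placed uniformly at random.  A synthetic-data generator
    produces incidence matrices, sampling effort and 3D coordinates under
    contrasting assembly scenarios (random fissure-network connectivity,
    deep-exclusive turnover, shallow-nested-in-deep, distinct slope fauna) so
    the whole pipeline can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
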