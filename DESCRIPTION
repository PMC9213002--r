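Package: embalign
Title: Cross-Modality Alignment and Identity Transfer for Embryonic
    Landmark Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfers cell identities from lineage-annotated point clouds of
    nuclear centroids onto anonymous clouds of the same developmental stage
    acquired in a different imaging modality.  Labeled clouds from several
    embryos are summarized as an ensemble anatomy model: Gabriel-graph
    adjacencies that are consistent across all members act as structural
    constraints, and cells whose presence varies because of divisions or
    deaths within a local temporal window form a list of inconsistent
    landmarks.  After landmark-based affine or thin-plate-spline
    pre-alignment and coherent-point-drift refinement, the unlabeled cloud is
    matched to each labeled member by linear assignment with iterative error
    correction, inconsistent landmarks are greedily modified
    (remove-death, merge-daughters, split-parent) whenever a modification
    reduces adjacency violations, and per-member answers are combined by a
    supermajority vote followed by one reiteration round seeded from
    confident matches.  A synthetic embryo generator with ground truth makes
    every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
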