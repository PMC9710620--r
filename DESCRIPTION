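Package: crossfun
Title: Cross-Species Protein Function Prediction from Co-Embedded
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts Gene Ontology annotations for proteins in a sparsely
    annotated target species by combining two sources of evidence: a
    diffusion-state-distance (DSD) embedding of the target species'
    protein-protein interaction network, and a MUNK-style co-embedding of
    the target network into a better-annotated model species' network,
    anchored on reciprocal-best-hit landmark pairs. Labels are assigned by
    a weighted two-source k-nearest-neighbour majority vote; six simple
    homology-transfer baselines, GO term specificity filtering,
    protein-centric F1-max and Resnik semantic-similarity evaluation, and
    standard plus inverted k-fold cross-validation are included, together
    with a synthetic paired-species data generator so the whole pipeline
    runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
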