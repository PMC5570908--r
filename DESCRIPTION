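Package: esibayes
Title: Naive Bayes Prediction of E3 Ubiquitin Ligase-Substrate Interactions
Version: 0.1.0
Authors@R:
    person("R.", "Developer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts directional interactions between E3 ubiquitin ligases
    and their substrates by integrating five heterogeneous evidence types
    (ortholog transfer of model-organism interactions, domain-pair and GO
    term-pair enrichment, triangle/quadrilateral loop counts in a
    protein-protein interaction network, and linear substrate-recognition
    motifs) as likelihood ratios in a naive Bayesian classifier. Includes
    likelihood-ratio calibration against gold-standard interaction sets,
    fivefold cross-validation with TP/FP and ROC/AUROC reporting, a
    pair-input (C1/C2/C3) test partition, a proteome-wide scanner, and a
    seeded synthetic-data generator with controllable planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    Biostrings,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
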