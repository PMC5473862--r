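Package: hetesimlpi
Title: Predicting lncRNA-Protein Interactions with Metapath HeteSim Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts long non-coding RNA (lncRNA) and protein interactions
    from a heterogeneous network built out of lncRNA-lncRNA co-expression
    similarity, lncRNA-protein association evidence, and protein-protein
    interaction confidence. Relatedness of each lncRNA-protein pair is
    measured by the HeteSim relevance score along every metapath of three
    to five node types; the per-path scores, damped geometrically for each
    extra hop, form the feature vector of a support vector machine
    classifier. Includes leave-one-out cross-validation and independent
    test evaluation (sensitivity, specificity, accuracy, precision, MCC,
    F1, ROC/AUC), a seeded block-structured synthetic network generator,
    and edge-list input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
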