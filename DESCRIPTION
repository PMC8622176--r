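Package: meshgcn
Title: Predicting MeSH Therapeutic-Use Classes of Drugs with Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts drug molecules given as SMILES strings into attributed
    molecular graphs (salt stripping, atom and bond featurization,
    deduplication), trains graph convolutional network classifiers for
    single-label and multi-label MeSH therapeutic-use class prediction with
    inverse-frequency class weighting and stratified or iterative pairwise
    multi-label cross validation, evaluates them with an imbalance-aware
    metric suite (balanced accuracy, Matthews correlation, AUROC, average
    precision, F-beta), and analyses multi-label predictions through MeSH
    class co-occurrence networks to surface drug repurposing candidates.
    Includes a synthetic labeled-SMILES generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    pROC,
    vegan,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
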