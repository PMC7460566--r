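Package: profilex
Title: Informative Gene Expression Profile Extraction by Clustering and
    Classifier Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stepwise extraction of informative gene expression profiles
    from a two-class (e.g. healthy versus tumor) expression matrix.
    Non-informative genes are removed by a boundary scan over per-gene
    variance, mean absolute expression and James-Stein shrinkage Shannon
    entropy, guided by a composite cluster-validity criterion (WB-index
    combined with the Calinski-Harabasz criterion) evaluated on the known
    sample classes. Remaining profiles are clustered with a level-wise
    binary self-organizing tree algorithm (SOTA) under correlation
    distance, the best cluster per hierarchical level is selected, a bank
    of binary classifiers (logistic regression, linear-kernel SVM,
    decision tree, random forest) scores each selected cluster, and a
    Mamdani fuzzy inference system fuses the classifier outputs into a
    final per-sample health-state decision. A seeded synthetic-data
    generator with planted correlated gene blocks makes the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
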