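Package: qsardnn
Title: Benchmarking Feed-Forward QSAR Neural Networks on Count-Fingerprint Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable benchmark pipeline for single-task QSAR regression with
    fully connected feed-forward neural networks on atom-pair (AP) and binding
    property pair (BP) count fingerprints. Provides hydrogen-suppressed molecular
    graphs with AP/BP atom typing and topological pair-count fingerprint
    generation, MMAC-style activity-table input/output with train/test descriptor
    vocabulary unification, squared-Pearson-correlation evaluation, a
    matrix-based multilayer perceptron trained with Adam, inverted dropout and
    ReLU activations, the best-epoch / multi-run evaluation protocol over a
    hyperparameter settings grid, and a synthetic molecular-activity data
    generator with controllable mechanism complexity, sparsity, covariate shift
    and floor censoring so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
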