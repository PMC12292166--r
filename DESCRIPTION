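Package: chaoswhale
Title: Dynamic Chaotic Whale Optimization and Progressive Ensemble Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hyperparameter optimization of image classifiers with the
    Whale Optimization Algorithm (WOA) and its chaotic variants, including a
    dynamic variant (DCWOA) that toggles between logistic and sine chaotic maps
    when the best fitness stagnates. Provides a five-dimensional mixed
    (continuous, log-scale, integer, categorical) search-space codec, an
    image-size-adaptive learning-rate scheduler, a progressive image-resizing
    training orchestrator over a pluggable trainer contract, seven classifier
    ensemble-fusion strategies (voting, weighted averaging with optimizer-tuned
    simplex weights, bagging, boosting, stacking, blending, and a hybrid
    combiner), standard classification metrics with rank-based AUC, and seeded
    synthetic generators (benchmark objectives, a surrogate fitness surface,
    correlated multi-model class-probability fixtures, labelled multi-resolution
    images) so the whole pipeline is exercisable without external data. A
    command-line interface exposes each component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
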