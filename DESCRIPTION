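Package: mdlgene
Title: Multi-Label Prediction of Aging-Related Disease Genes via Network
    Embedding and Modular Deep Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts associations between genes and aging-related diseases
    by combining diffusion-based network embedding with a two-stage modular
    neural classifier. Heterogeneous gene-gene networks are summarised by
    random walk with restart diffusion states and compressed into a shared
    low-dimensional embedding (the Mashup approach); each feature dataset is
    then encoded by its own small neural network whose bottleneck activations
    are fused by a second network into scores for a hierarchical multi-label
    disease annotation. Includes per-label AUROC cross-validation, naive and
    logistic-regression baselines, seed-replicated statistical method
    comparison, consensus recommendation of unannotated candidate genes, and
    a synthetic-data generator with planted community and label signal for
    end-to-end benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
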