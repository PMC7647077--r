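Package: netten
Title: Personalized Gene Regulatory Network Tensors and Supervised Subspace Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sample-specific gene regulatory networks by Gaussian
    kernel-weighted varying-coefficient elastic-net regression, stacks the
    per-sample coefficient networks into a third-order tensor, and learns a
    supervised low-dimensional orthonormal subspace of that tensor jointly
    with a response-prediction head. Downstream interpretation tools extract
    differential-adjacency marker genes between regions of a learned
    component, compute regulatory effects (RE) and regulatory effect changes
    (REC) of edges along a scalar modulator, group markers by PCA of the REC
    matrix, and test tissue association of sample regions. A seeded
    synthetic-data generator produces modulator-driven expression data and
    planted network tensors so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
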