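Package: aime
Title: Autoencoder-Based Integrative Multi-Omics Embedding with
    Confounder Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts a low-dimensional nonlinear embedding of one omics
    data matrix that best preserves the information needed to reconstruct
    a second omics matrix measured on the same samples, while adjusting
    for clinical confounders injected at the bottleneck layer of an
    asymmetric autoencoder. Input features and input-output feature pairs
    are ranked by permutation importance, and significant ones are
    selected with a gamma-null local false discovery rate procedure.
    Includes hyperparameter tuning by multivariate non-normality of the
    embedding (Mardia's skewness and kurtosis), a nonlinear paired-data
    simulation generator with known ground truth, and precision-recall
    and k-nearest-neighbour purity evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
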