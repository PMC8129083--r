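Package: xoxdr
Title: Supervised Linear Dimensionality Reduction for Wide Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the XOX family of supervised linear dimensionality
    reduction methods for wide (p >= n) biomedical data: Linear Optimal
    Low-rank projection (LOL), its robust median-location variant, the
    per-class-covariance variant QOQ, and the sparse-random-projection
    variant LFL, together with baseline embeddings (PCA, reduced-rank LDA,
    random projections, CCA, PLS), Gaussian discriminant classifiers (LDA,
    QDA), Chernoff-information evaluation of embeddings between Gaussian
    class-conditionals, seeded samplers for canonical wide-data simulation
    settings, and a cross-validated misclassification-versus-dimension
    benchmarking harness with Cohen's kappa effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
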