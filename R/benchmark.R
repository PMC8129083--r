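# Seeded train/test benchmark over simulation settings: the procedure used
# to compare embedding + classifier pipelines on held-out data.

#' Held-out misclassification of embedding pipelines on a setting
#'
#' For each seed, draws a training sample from `setting` and a clean test
#' sample from `test_setting` (defaults to `setting`; contamination is only
#' ever applied to the train split), fits every pipeline at its embedding
#' dimension, trains the pipeline's Gaussian classifier on the embedded
#' training data, and scores the embedded test data.
#'
#' @param setting A [make_setting()] object to train on.
#' @param specs Named list of pipeline specs; each a list with `method`
#'   (registry name), and optionally `classifier` (`"lda"` default or
#'   `"qda"`), `location` (`"median"` default), `d` (overrides the common
#'   dimension), `sparsity`. The list names label the output rows.
#' @param d Common embedding dimension.
#' @param n_train,n_test Train and test sample sizes.
#' @param seeds Integer vector of seeds; one train/test draw per seed.
#' @param test_setting Optional alternative setting for the test draw.
#' @return A tibble with columns `seed`, `method`, `error`.
#' @export
benchmark_errors <- function(setting, specs, d, n_train, n_test, seeds,
                             test_setting = NULL) {
  stopifnot(length(names(specs)) == length(specs))
  purrr::map_dfr(as.integer(seeds), function(s) {
    train <- sample_from(setting, n_train, seed = s, split = "train")
    test <- sample_from(test_setting %||% setting, n_test,
                        seed = s + 100000L, split = "test")
    purrr::imap_dfr(specs, function(sp, label) {
      fitter <- method_registry(sp$method,
                                location = sp$location %||% "median",
                                sparsity = sp$sparsity, seed = s)
      model <- fitter(train, sp$d %||% d)
      z_tr <- transform_data(model, train$x)
      clf <- fit_gaussian_classifier(z_tr, train$y,
                                     kind = sp$classifier %||% "lda")
      pred <- predict(clf, transform_data(model, test$x))
      tibble::tibble(seed = s, method = label,
                     error = mean(as.character(pred) !=
                                    as.character(test$y)))
    })
  })
}
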