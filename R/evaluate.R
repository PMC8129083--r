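# Cross-validated misclassification-vs-dimension curves, Cohen's kappa
# effect sizes, ranks, and the benchmark comparison procedure.

# Built-in method registry: each entry fits a projection at dimension d.
method_registry <- function(name, location, sparsity, seed) {
  switch(
    name,
    lol = function(data, d) fit_lol(data, d = d, location = location,
                                    seed = seed),
    qoq = function(data, d) fit_qoq(data, d = d, location = location,
                                    seed = seed),
    lfl = function(data, d) fit_lfl(data, d = d, location = location,
                                    sparsity = sparsity, seed = seed),
    rrlda = function(data, d) fit_rrlda(data, d = d, seed = seed),
    pca = function(data, d) fit_pca(data, d = d, seed = seed),
    rp = function(data, d) fit_rp(data$p, d = d, sparsity = sparsity,
                                  seed = seed),
    cca = function(data, d) fit_cca(data, d = d),
    pls = function(data, d) fit_pls(data, d = d),
    stop("unknown method: ", name, call. = FALSE)
  )
}

# Stratified fold assignment: shuffles within class (seeded) and deals fold
# ids round-robin with a running offset across classes, so global fold sizes
# differ by at most one and class proportions by at most one sample.
stratified_folds <- function(data, k, seed) {
  fold <- integer(data$n)
  offset <- 0L
  with_seed(seed, {
    for (rows in data$class_index) {
      rows <- rows[sample.int(length(rows))]
      ids <- ((seq_along(rows) - 1L + offset) %% k) + 1L
      fold[rows] <- ids
      offset <- (offset + length(rows)) %% k
    }
  })
  fold
}

#' Cross-validated error-versus-dimension curves
#'
#' Runs stratified k-fold cross-validation for each embedding method over a
#' grid of dimensions. Per fold, each method is fit exactly once at
#' `max(dims)` and truncated for the smaller dimensions (the nested
#' hyperparameter property), the held-out fold is projected with the
#' train-fold model, and a Gaussian discriminant classifier is trained on
#' the embedded training fold. The selected dimension per method is the one
#' with the lowest mean cross-validated error (ties break to the smallest),
#' and Cohen's kappa is reported at that dimension from the pooled
#' cross-validated confusion table.
#'
#' @param data A [labeled_dataset()] (or matrix plus `y`).
#' @param methods Character vector of built-in method names (`"lol"`,
#'   `"qoq"`, `"lfl"`, `"rrlda"`, `"pca"`, `"rp"`, `"cca"`, `"pls"`), or a
#'   named list of functions `f(data, d)` returning a `projection_model`.
#' @param dims Integer vector of embedding dimensions (all `<= p`).
#' @param folds Number of folds `k >= 2`.
#' @param classifier `"lda"` or `"qda"`.
#' @param seed Seed for fold assignment and any stochastic fits.
#' @param location Location estimator forwarded to the XOX fits.
#' @param sparsity Sparsity forwarded to RP/LFL fits.
#' @param y Labels when `data` is a bare matrix.
#' @return An object of class `eval_curves`: a list with `curves` (tibble:
#'   method, dim, fold, error), `summary` (tibble: method, dim, mean_error,
#'   kappa), `selected` (tibble: method, selected_dim, mean_error, kappa),
#'   `folds`, `classifier`, and `fit_counts` (fits per method, for the
#'   nested-fit contract).
#' @export
crossval_curves <- function(data, methods, dims, folds = 5L,
                            classifier = c("lda", "qda"), seed = 1L,
                            location = "median", sparsity = NULL,
                            y = NULL) {
  data <- as_dataset(data, y)
  classifier <- match.arg(classifier)
  dims <- sort(unique(as.integer(dims)))
  if (any(dims < 1L) || max(dims) > data$p) {
    stop("dims must lie in [1, p]", call. = FALSE)
  }
  k <- as.integer(folds)
  if (k < 2L) stop("folds must be >= 2", call. = FALSE)
  min_class <- min(vapply(data$class_index, length, integer(1)))
  if (k > min_class) {
    stop("a fold would lose a class (smallest class has ", min_class,
         " samples); use fewer folds", call. = FALSE)
  }
  if (is.character(methods)) {
    fitters <- lapply(methods, method_registry, location = location,
                      sparsity = sparsity, seed = seed)
    names(fitters) <- methods
  } else {
    fitters <- methods
    if (is.null(names(fitters)) || any(!nzchar(names(fitters)))) {
      stop("custom methods must be a named list of fitting functions",
           call. = FALSE)
    }
  }
  fold_id <- stratified_folds(data, k, seed)
  C <- n_classes(data)
  d_max <- max(dims)
  n_dims <- length(dims)
  fit_counts <- stats::setNames(integer(length(fitters)), names(fitters))
  err <- array(NA_real_, c(length(fitters), n_dims, k),
               dimnames = list(names(fitters), dims, NULL))
  conf <- array(0, c(length(fitters), n_dims, C, C))

  for (f in seq_len(k)) {
    tr_rows <- which(fold_id != f)
    te_rows <- which(fold_id == f)
    y_tr <- data$y[tr_rows]
    if (length(unique(y_tr)) < C || length(unique(data$y[te_rows])) < 1L) {
      stop("a fold lost a class entirely; use fewer folds", call. = FALSE)
    }
    train <- labeled_dataset(data$x[tr_rows, , drop = FALSE],
                             as.character(y_tr))
    x_te <- data$x[te_rows, , drop = FALSE]
    y_te <- as.character(data$y[te_rows])
    for (m in seq_along(fitters)) {
      model <- fitters[[m]](train, d_max)
      fit_counts[m] <- fit_counts[m] + 1L
      for (di in seq_len(n_dims)) {
        sub <- nested_truncate(model, dims[di])
        z_tr <- transform_data(sub, train$x)
        clf <- fit_gaussian_classifier(z_tr, train$y, kind = classifier)
        pred <- as.character(predict(clf, transform_data(sub, x_te)))
        err[m, di, f] <- mean(pred != y_te)
        tab <- table(factor(y_te, levels = data$classes),
                     factor(pred, levels = data$classes))
        conf[m, di, , ] <- conf[m, di, , ] + unclass(tab)
      }
    }
  }

  curves <- tidyr::expand_grid(method = names(fitters), dim = dims,
                               fold = seq_len(k))
  curves$error <- purrr::pmap_dbl(curves, function(method, dim, fold) {
    err[method, as.character(dim), fold]
  })
  summary_tb <- dplyr::summarise(
    dplyr::group_by(curves, .data$method, .data$dim),
    mean_error = mean(.data$error), .groups = "drop"
  )
  kappa_at <- function(m, di) cohens_kappa(conf[m, di, , ])
  summary_tb$kappa <- purrr::map2_dbl(
    match(summary_tb$method, names(fitters)),
    match(summary_tb$dim, dims), kappa_at
  )
  selected <- dplyr::arrange(summary_tb, .data$method, .data$mean_error,
                             .data$dim)
  selected <- dplyr::slice_head(dplyr::group_by(selected, .data$method),
                                n = 1L)
  selected <- dplyr::rename(dplyr::ungroup(selected), selected_dim = "dim")
  structure(
    list(curves = curves, summary = summary_tb, selected = selected,
         folds = k, classifier = classifier, dims = dims,
         classes = data$classes, fit_counts = fit_counts,
         confusion = conf, seed = seed),
    class = "eval_curves"
  )
}

#' @export
print.eval_curves <- function(x, ...) {
  cat("<eval_curves> ", length(x$fit_counts), " methods x ",
      length(x$dims), " dims, ", x$folds, "-fold CV, classifier=",
      x$classifier, "\n", sep = "")
  print(x$selected)
  invisible(x)
}

#' Lowest-mean-error dimension of a curve
#'
#' @param curve An `eval_curves` object (per-method) or a tibble with
#'   columns `dim` and `mean_error`.
#' @param method Method name when `curve` is an `eval_curves` object with
#'   several methods.
#' @return The dimension minimizing mean error; ties break to the smallest.
#' @export
select_dim <- function(curve, method = NULL) {
  tb <- if (inherits(curve, "eval_curves")) curve$summary else curve
  if (!is.null(method)) tb <- tb[tb$method == method, ]
  if (nrow(tb) == 0L) stop("empty curve", call. = FALSE)
  tb <- tb[order(tb$dim), ]
  tb$dim[which.min(tb$mean_error)]
}

#' Cohen's kappa from a confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`: 0 for a classifier
#' equivalent to chance given the marginals, 1 for perfect agreement.
#'
#' @param confusion A `C x C` nonnegative count table (rows: truth, columns:
#'   prediction).
#' @return Kappa. Degenerate marginals (`p_e = 1`) return 0 with a warning.
#' @examples
#' cohens_kappa(matrix(c(40, 20, 10, 30), 2)) # 0.4
#' @export
cohens_kappa <- function(confusion) {
  m <- as.matrix(unclass(confusion))
  if (nrow(m) != ncol(m) || any(m < 0)) {
    stop("confusion must be a square nonnegative count table",
         call. = FALSE)
  }
  n <- sum(m)
  if (n <= 0) stop("confusion table is empty", call. = FALSE)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate marginals (p_e = 1); kappa defined as 0",
            call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Effect sizes, ranks, and paired signed-rank comparison across datasets
#'
#' For each dataset and method, computes the effect size
#' `kappa(reference) - kappa(method)` at each method's own selected
#' dimension (negative favors the method), per-dataset ranks of the
#' selected-dimension mean errors (1 = best, ties get average ranks), and
#' two-sided paired Wilcoxon signed-rank p-values between every method pair
#' across datasets (exact null for small counts; zero differences dropped).
#'
#' @param results A list of [crossval_curves()] objects, one per dataset
#'   (at least 2 for the signed-rank test). Names are used as dataset ids.
#' @param reference Reference method name present in every result.
#' @return A list of class `xox_comparison`: `table` (tibble: dataset,
#'   method, selected_dim, mean_error, kappa, effect, rank) and `wilcoxon`
#'   (tibble: method1, method2, p_value).
#' @export
effect_size_and_ranks <- function(results, reference = "pca") {
  if (inherits(results, "eval_curves")) results <- list(results)
  if (length(results) < 2L) {
    stop("need results from at least 2 datasets for the signed-rank test",
         call. = FALSE)
  }
  ids <- names(results) %||% as.character(seq_along(results))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  rows <- purrr::map2_dfr(results, ids, function(res, id) {
    sel <- res$selected
    if (!reference %in% sel$method) {
      stop("reference method '", reference, "' missing from dataset ", id,
           call. = FALSE)
    }
    kref <- sel$kappa[sel$method == reference]
    tibble::tibble(dataset = id, method = sel$method,
                   selected_dim = sel$selected_dim,
                   mean_error = sel$mean_error, kappa = sel$kappa,
                   effect = kref - sel$kappa)
  })
  rows <- dplyr::mutate(dplyr::group_by(rows, .data$dataset),
                        rank = rank(.data$mean_error, ties.method = "average"))
  rows <- dplyr::ungroup(rows)
  methods <- unique(rows$method)
  pairs <- utils::combn(methods, 2L, simplify = FALSE)
  wil <- purrr::map_dfr(pairs, function(pr) {
    e1 <- rows$mean_error[rows$method == pr[1L]][order(rows$dataset[rows$method == pr[1L]])]
    e2 <- rows$mean_error[rows$method == pr[2L]][order(rows$dataset[rows$method == pr[2L]])]
    pv <- if (all(e1 == e2)) 1 else suppressWarnings(
      stats::wilcox.test(e1, e2, paired = TRUE,
                         exact = length(e1) <= 25L)$p.value
    )
    tibble::tibble(method1 = pr[1L], method2 = pr[2L], p_value = pv)
  })
  structure(list(table = rows, wilcoxon = wil, reference = reference),
            class = "xox_comparison")
}

#' @export
print.xox_comparison <- function(x, ...) {
  cat("<xox_comparison> reference =", x$reference, "\n")
  print(x$table)
  invisible(x)
}

#' Write a machine-readable benchmark report
#'
#' JSON containing, per method: dimensions, per-fold errors, mean errors,
#' kappa per dimension, and the selected dimension; plus effect sizes when
#' a comparison is supplied.
#'
#' @param results An `eval_curves` object or a list of them.
#' @param path Output path.
#' @param comparison Optional [effect_size_and_ranks()] result.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, comparison = NULL) {
  if (inherits(results, "eval_curves")) results <- list(results)
  if (length(results) == 0L) stop("empty results", call. = FALSE)
  ids <- names(results) %||% as.character(seq_along(results))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  payload <- list(
    version = "xoxdr-report-v1",
    datasets = stats::setNames(lapply(results, function(res) {
      per_method <- lapply(stats::setNames(nm = unique(res$summary$method)),
                           function(m) {
        sm <- res$summary[res$summary$method == m, ]
        cv <- res$curves[res$curves$method == m, ]
        list(dims = sm$dim,
             mean_error = sm$mean_error,
             kappa = sm$kappa,
             fold_errors = lapply(split(cv$error, cv$dim), unname),
             selected_dim = res$selected$selected_dim[
               res$selected$method == m],
             kappa_at_selected = res$selected$kappa[
               res$selected$method == m])
      })
      list(folds = res$folds, classifier = res$classifier,
           methods = per_method)
    }), ids)
  )
  if (!is.null(comparison)) {
    payload$comparison <- list(
      reference = comparison$reference,
      table = comparison$table,
      wilcoxon = comparison$wilcoxon
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path.
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(rep$version) || rep$version != "xoxdr-report-v1") {
    stop("parse error: unsupported report version", call. = FALSE)
  }
  rep
}
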