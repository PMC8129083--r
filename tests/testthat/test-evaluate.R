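fake_curves <- function(methods, kappas, errors, dims = NULL) {
  structure(list(selected = tibble::tibble(
    method = methods,
    selected_dim = dims %||% rep(2L, length(methods)),
    mean_error = errors, kappa = kappas
  )), class = "eval_curves")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("well-separated clouds cross-validate to zero error", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 10, 0.1), 20, 2))
  })
  d <- labeled_dataset(x, rep(c("a", "b"), each = 20))
  res <- crossval_curves(d, "pca", dims = 1, folds = 2, seed = 1)
  expect_equal(res$summary$mean_error, 0)
})

test_that("stratified folds balance size and class composition", {
  withr::with_seed(3, {
    x <- matrix(rnorm(23 * 4), 23, 4)
  })
  y <- c(rep("a", 14), rep("b", 9))
  d <- labeled_dataset(x, y)
  folds <- xoxdr:::stratified_folds(d, 5, seed = 9)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  per_class <- table(folds, y)
  for (cl in c("a", "b")) {
    expect_lte(max(per_class[, cl]) - min(per_class[, cl]), 1)
  }
  expect_error(crossval_curves(d, "pca", dims = 1, folds = 12, seed = 1),
               "fewer folds")
})

test_that("each method is fit once per fold and truncated across dims", {
  d <- rand_dataset(40, 10, seed = 6, shift = 3)
  counter <- new.env()
  counter$n <- 0L
  probe <- list(probe = function(data, dd) {
    counter$n <- counter$n + 1L
    fit_lol(data, d = dd, location = "mean")
  })
  res <- crossval_curves(d, probe, dims = c(1, 2, 4, 6), folds = 4,
                         seed = 2)
  expect_equal(counter$n, 4L) # one fit per fold, all dims by truncation
  expect_equal(unname(res$fit_counts["probe"]), 4L)
  # mean error is exactly the mean of the fold errors
  for (dd in c(1, 2, 4, 6)) {
    folds_err <- res$curves$error[res$curves$dim == dd]
    expect_equal(res$summary$mean_error[res$summary$dim == dd],
                 mean(folds_err), tolerance = 1e-12)
  }
})

test_that("cohens_kappa matches marginal arithmetic", {
  expect_equal(cohens_kappa(diag(c(10, 20, 5))), 1)
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4,
               tolerance = 1e-12)
  # independent marginals: kappa 0 up to rounding
  ind <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cohens_kappa(ind), 0, tolerance = 1e-12)
  expect_warning(k <- cohens_kappa(matrix(c(7, 0, 0, 0), 2)),
                 "degenerate")
  expect_equal(k, 0)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("select_dim takes the lowest mean error, ties to smallest d", {
  tb <- tibble::tibble(method = "m", dim = c(1, 3, 7, 9),
                       mean_error = c(0.5, 0.2, 0.2, 0.4))
  expect_equal(select_dim(tb), 3)
  tb2 <- tibble::tibble(method = "m", dim = 1:4,
                        mean_error = c(0.9, 0.6, 0.3, 0.1))
  expect_equal(select_dim(tb2), 4)
  # random curves against a linear-scan oracle
  withr::with_seed(8, {
    for (rep in 1:20) {
      e <- round(runif(6), 2)
      tbr <- tibble::tibble(method = "m", dim = sample(1:20, 6),
                            mean_error = e)
      got <- select_dim(tbr)
      srt <- tbr[order(tbr$dim), ]
      oracle <- srt$dim[which.min(srt$mean_error)]
      expect_equal(got, oracle)
    }
  })
})

test_that("effect sizes, ranks, and the signed-rank test behave", {
  r1 <- fake_curves(c("pca", "lol", "rp"), kappas = c(0.6, 0.8, 0.6),
                    errors = c(0.2, 0.1, 0.3))
  r2 <- fake_curves(c("pca", "lol", "rp"), kappas = c(0.5, 0.7, 0.4),
                    errors = c(0.25, 0.15, 0.35))
  cmp <- effect_size_and_ranks(list(a = r1, b = r2), reference = "pca")
  tb <- cmp$table
  expect_equal(tb$effect[tb$dataset == "a" & tb$method == "lol"], -0.2,
               tolerance = 1e-12)
  expect_equal(tb$effect[tb$dataset == "a" & tb$method == "rp"], 0,
               tolerance = 1e-12)
  expect_equal(tb$rank[tb$dataset == "a"], c(2, 1, 3))
  expect_true(all(c("method1", "method2", "p_value") %in%
                    names(cmp$wilcoxon)))
  expect_true(all(cmp$wilcoxon$p_value >= 0 & cmp$wilcoxon$p_value <= 1))
  expect_error(effect_size_and_ranks(list(r1), reference = "pca"),
               "at least 2")
  expect_error(effect_size_and_ranks(list(a = r1, b = r2),
                                     reference = "nope"), "missing")
})

test_that("reports round-trip the curves they were given", {
  d <- rand_dataset(30, 8, seed = 12, shift = 3)
  res <- crossval_curves(d, c("lol", "pca"), dims = c(1, 2), folds = 3,
                         seed = 5)
  f <- tempfile(fileext = ".json")
  write_report(res, f)
  rep <- read_report(f)
  ms <- rep$datasets[["1"]]$methods
  expect_equal(length(ms$lol$dims), 2)
  expect_equal(ms$lol$mean_error,
               res$summary$mean_error[res$summary$method == "lol"])
  expect_equal(ms$pca$selected_dim,
               res$selected$selected_dim[res$selected$method == "pca"])
  expect_error(write_report(list(), tempfile()), "empty")
  # comparison block carries one effect per non-reference method
  r1 <- fake_curves(c("pca", "lol"), c(0.6, 0.8), c(0.2, 0.1))
  r2 <- fake_curves(c("pca", "lol"), c(0.5, 0.7), c(0.25, 0.15))
  cmp <- effect_size_and_ranks(list(a = r1, b = r2))
  f2 <- tempfile(fileext = ".json")
  write_report(res, f2, comparison = cmp)
  rep2 <- read_report(f2)
  eff <- rep2$comparison$table
  expect_equal(sum(eff$method != "pca"), 2) # one per dataset
})

test_that("tidy and glance expose curves and selections", {
  d <- rand_dataset(24, 6, seed = 14, shift = 3)
  res <- crossval_curves(d, "lol", dims = c(1, 2), folds = 3, seed = 7)
  td <- generics::tidy(res)
  expect_true(all(c("method", "dim", "fold", "error") %in% names(td)))
  expect_equal(nrow(td), 2 * 3)
  gl <- generics::glance(res)
  expect_true(all(c("selected_dim", "kappa") %in% names(gl)))
  m <- fit_lol(d, d = 2)
  expect_equal(nrow(generics::tidy(m)), 2)
  expect_equal(generics::glance(m)$method, "lol")
})
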