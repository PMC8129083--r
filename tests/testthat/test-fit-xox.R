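test_that("LOL on the 4-point hand case gives the identity columns", {
  m <- fit_lol(four_point_data(), d = 2, location = "mean")
  expect_equal(m$W, cbind(c(1, 0), c(0, 1)), tolerance = 1e-12)
  expect_equal(m$column_kind, c("mean_diff", "shared_eig"))
})

test_that("LOL eigenvector block matches the dense SVD oracle", {
  d <- rand_dataset(20, 50, seed = 11)
  m <- fit_lol(d, d = 6, location = "mean")
  # oracle: eigenvectors of the materialized class-centered covariance
  S <- centered_cov_oracle(d$x, as.character(d$y))
  oracle <- eigvec_oracle(S, 5)
  expect_lt(max_col_diff_aligned(m$W[, 2:6], oracle), 1e-8)
  expect_equal(colSums(m$W^2), rep(1, 6))
})

test_that("three-class fits put the mean-difference block first", {
  st <- make_setting("trunk3", p = 40)
  tr <- sample_from(st, 90, seed = 2)
  m2 <- fit_lol(tr, d = 2)
  expect_equal(m2$column_kind, c("mean_diff", "mean_diff"))
  m5 <- fit_lol(tr, d = 5)
  expect_equal(m5$column_kind[1:2], c("mean_diff", "mean_diff"))
  expect_equal(m5$column_kind[3:5], rep("shared_eig", 3))
  # d <= C - 1 silently yields a means-only projection
  m1 <- fit_lol(tr, d = 1)
  expect_equal(m1$column_kind, "mean_diff")
})

test_that("QOQ pools per-class eigenvectors sorted by singular value", {
  st <- make_setting("cross", p = 20)
  tr <- sample_from(st, 120, seed = 6)
  m <- fit_qoq(tr, d = 5, location = "mean")
  expect_equal(m$column_kind[1], "mean_diff")
  # oracle: per-class singular values of the class-centered blocks
  sv_by_class <- lapply(tr$class_index, function(rows) {
    Mk <- scale(tr$x[rows, ], center = TRUE, scale = FALSE)
    svd(Mk)$d / sqrt(length(rows))
  })
  labels <- unlist(lapply(seq_along(sv_by_class), function(k) {
    rep(paste0("class", k - 1L, "_eig"), length(sv_by_class[[k]]))
  }))
  expected <- labels[order(-unlist(sv_by_class))][1:4]
  expect_equal(m$column_kind[2:5], expected)
  # eigenvector columns match per-class dense oracles up to sign
  ord <- order(-unlist(sv_by_class))[1:4]
  pos <- unlist(lapply(sv_by_class, seq_along))[ord]
  cls <- rep(seq_along(sv_by_class), lengths(sv_by_class))[ord]
  for (j in seq_len(4)) {
    rows <- tr$class_index[[cls[j]]]
    Sk <- crossprod(scale(tr$x[rows, ], center = TRUE, scale = FALSE)) /
      length(rows)
    v <- eigvec_oracle(Sk, pos[j])[, pos[j]]
    expect_lt(min(sqrt(sum((m$W[, j + 1] - v)^2)),
                  sqrt(sum((m$W[, j + 1] + v)^2))), 1e-8)
  }
})

test_that("rrLDA equals the LOL eigenvector block shifted by one", {
  d <- rand_dataset(30, 25, seed = 13)
  r <- fit_rrlda(d, d = 4)
  l <- fit_lol(d, d = 5, location = "mean")
  expect_identical(r$W, l$W[, 2:5])
  expect_equal(r$column_kind, rep("shared_eig", 4))
})

test_that("rrLDA is invariant to shifting one class by a constant", {
  d <- rand_dataset(24, 15, seed = 17)
  x2 <- d$x
  rows <- d$class_index[[2]]
  x2[rows, ] <- sweep(x2[rows, , drop = FALSE], 2, rnorm(15) * 5)
  d2 <- labeled_dataset(x2, as.character(d$y))
  expect_lt(max_col_diff_aligned(fit_rrlda(d2, d = 3)$W,
                                 fit_rrlda(d, d = 3)$W), 1e-8)
})

test_that("truncation of exact fits is bit-identical to refitting", {
  d <- rand_dataset(40, 60, seed = 19)
  for (fitter in list(
    function(dd) fit_lol(dd, d = 12),
    function(dd) fit_lol(dd, d = 12, location = "mean"),
    function(dd) fit_qoq(dd, d = 12, location = "mean"),
    function(dd) fit_lfl(dd, d = 12, seed = 4),
    function(dd) fit_rrlda(dd, d = 12)
  )) {
    big <- fitter(d)
    for (dp in c(1L, 5L, 11L)) {
      small_refit <- switch(big$method,
        lol = fit_lol(d, d = dp, location = big$fit_meta$location),
        qoq = fit_qoq(d, d = dp, location = big$fit_meta$location),
        lfl = fit_lfl(d, d = dp, seed = 4),
        rrlda = fit_rrlda(d, d = dp))
      expect_identical(nested_truncate(big, dp)$W, small_refit$W)
    }
  }
})

test_that("dimension bounds are enforced", {
  d <- rand_dataset(10, 5, seed = 1)
  expect_error(fit_lol(d, d = 6), "exceeds")
  expect_error(fit_lol(d, d = 0), ">= 1")
  expect_error(fit_rrlda(d, d = 6), "exceeds")
})

test_that("mean-location fits are rotation-equivariant", {
  d <- rand_dataset(18, 12, seed = 23)
  Q <- xoxdr:::random_orthogonal(12, seed = 31)
  d_rot <- labeled_dataset(d$x %*% t(Q), as.character(d$y))
  for (pair in list(
    list(fit_lol(d, d = 4, location = "mean"),
         fit_lol(d_rot, d = 4, location = "mean")),
    list(fit_rrlda(d, d = 4), fit_rrlda(d_rot, d = 4)),
    list(fit_pca(d, d = 4), fit_pca(d_rot, d = 4))
  )) {
    expect_lt(max_col_diff_aligned(pair[[2]]$W, Q %*% pair[[1]]$W), 1e-8)
  }
})

test_that("the randomized solver recovers a well-separated subspace", {
  # spiked design: three dominant directions far above the noise floor
  withr::with_seed(41, {
    n <- 60; p <- 200
    U <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
    x <- matrix(rnorm(n * p), n, p) + (matrix(rnorm(n * 3), n, 3) * 15) %*% t(U)
    y <- rep_len(0:1, n)
  })
  d <- labeled_dataset(x, y)
  ex <- fit_rrlda(d, d = 3, solver = "exact")
  rz <- fit_rrlda(d, d = 3, solver = "randomized", seed = 5)
  # principal angles between the two 3-dim subspaces
  sv <- svd(crossprod(ex$W, rz$W))$d
  expect_gt(min(sv), 1 - 1e-6)
})

test_that("large-p fits stay in factorized form", {
  # p far beyond anything a materialized p x p covariance could support
  # in this footprint; completes quickly because only the thin SVD is used
  d <- rand_dataset(30, 20000, seed = 3)
  m <- fit_lol(d, d = 4, location = "mean")
  expect_equal(dim(m$W), c(20000, 4))
  expect_equal(colSums(m$W^2), rep(1, 4))
})

test_that("optional Gram-Schmidt yields an orthonormal basis", {
  d <- rand_dataset(25, 10, seed = 29)
  m <- fit_lol(d, d = 4, location = "mean", orthogonalize = TRUE)
  expect_lt(max(abs(crossprod(m$W) - diag(4))), 1e-10)
})
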