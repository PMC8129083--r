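test_that("symmetric 1-D classes give a threshold at zero", {
  z <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  clf <- fit_gaussian_classifier(z, y, kind = "lda")
  expect_equal(as.character(predict(clf, matrix(c(-0.01, 0.01), ncol = 1))),
               c("0", "1"))
  # equidistant point with equal priors breaks the tie to class 0
  expect_equal(as.character(predict(clf, matrix(0, 1, 1))), "0")
})

test_that("LDA recovers the Fisher direction", {
  withr::with_seed(15, {
    n <- 400
    y <- rep_len(0:1, n)
    A <- matrix(c(2, 0.6, 0.6, 1), 2)
    z <- matrix(rnorm(n * 2), n, 2) %*% chol(A)
    z[y == 1, ] <- z[y == 1, ] + c(1.5, 0.5)
  })
  clf <- fit_gaussian_classifier(z, y, kind = "lda")
  # plug-in boundary normal: S^-1 (m1 - m0)
  w <- solve(clf$cov, clf$means[, 2] - clf$means[, 1])
  # oracle from raw data, no classifier code involved
  m0 <- colMeans(z[y == 0, ]); m1 <- colMeans(z[y == 1, ])
  zc <- z
  zc[y == 0, ] <- sweep(z[y == 0, ], 2, m0)
  zc[y == 1, ] <- sweep(z[y == 1, ], 2, m1)
  S <- crossprod(zc) / n
  w_oracle <- solve(S, m1 - m0)
  expect_lt(max(abs(w / sqrt(sum(w^2)) - w_oracle / sqrt(sum(w_oracle^2)))),
            1e-6)
})

test_that("QDA decision sits at the analytic quadratic root", {
  # exact-parameter classifier: N(0, 1) vs N(0, 4) in 1-D, equal priors
  clf <- structure(
    list(kind = "qda", priors = c(`0` = 0.5, `1` = 0.5),
         means = matrix(0, 1, 2),
         cov = list(matrix(1, 1, 1), matrix(4, 1, 1)),
         classes = c("0", "1"), d = 1L),
    class = "gaussian_classifier")
  # log f0(z) = log f1(z)  =>  z^2 (1 - 1/4) = 2 log 2  =>  |z| = root
  root <- sqrt(2 * log(2) / (1 - 1 / 4))
  eps <- 1e-6
  got <- as.character(predict(clf, matrix(c(root - eps, root + eps,
                                            -root - eps, -root + eps),
                                          ncol = 1)))
  expect_equal(got, c("0", "1", "1", "0"))
})

test_that("predictions agree with a brute-force density oracle", {
  withr::with_seed(25, {
    n <- 120
    y <- rep_len(c("u", "v", "w"), n)
    z <- matrix(rnorm(n * 3), n, 3)
    z[y == "v", 1] <- z[y == "v", 1] + 2
    z[y == "w", 2] <- z[y == "w", 2] * 2 + 1
    z_new <- matrix(rnorm(500 * 3), 500, 3)
  })
  for (kind in c("lda", "qda")) {
    clf <- fit_gaussian_classifier(z, y, kind = kind)
    pred <- predict(clf, z_new)
    dens <- vapply(seq_along(clf$classes), function(k) {
      S <- if (kind == "lda") clf$cov else clf$cov[[k]]
      Si <- solve(S)
      diff <- sweep(z_new, 2, clf$means[, k])
      log(clf$priors[k]) - 0.5 * rowSums((diff %*% Si) * diff) -
        0.5 * determinant(S)$modulus
    }, numeric(500))
    oracle <- clf$classes[max.col(dens, ties.method = "first")]
    expect_equal(as.character(pred), oracle)
  }
})

test_that("classification is equivariant under affine maps", {
  withr::with_seed(35, {
    n <- 80
    y <- rep_len(0:1, n)
    z <- matrix(rnorm(n * 3), n, 3)
    z[y == 1, ] <- z[y == 1, ] + c(2, -1, 0.5)
    R <- matrix(rnorm(9), 3, 3) + diag(3) * 2
    b <- rnorm(3)
    z_new <- matrix(rnorm(200 * 3), 200, 3)
  })
  for (kind in c("lda", "qda")) {
    clf <- fit_gaussian_classifier(z, y, kind = kind)
    clf_t <- fit_gaussian_classifier(sweep(z %*% R, 2, -b), y, kind = kind)
    expect_equal(as.character(predict(clf_t, sweep(z_new %*% R, 2, -b))),
                 as.character(predict(clf, z_new)))
  }
})

test_that("plug-in LDA error converges to the closed form", {
  withr::with_seed(45, {
    n <- 2000
    y <- rep_len(0:1, n)
    z <- matrix(rnorm(n * 2), n, 2)
    z[y == 1, 1] <- z[y == 1, 1] + 2
  })
  clf <- fit_gaussian_classifier(z, y, kind = "lda")
  # simulate a large test set from the classifier's own fitted model
  withr::with_seed(46, {
    m_t <- 40000
    y_t <- rep_len(0:1, m_t)
    R <- chol(clf$cov)
    z_t <- matrix(rnorm(m_t * 2), m_t, 2) %*% R
    z_t <- z_t + t(clf$means[, y_t + 1])
  })
  err <- mean(as.character(predict(clf, z_t)) != as.character(y_t))
  delta <- clf$means[, 2] - clf$means[, 1]
  s <- drop(t(delta) %*% solve(clf$cov, delta))
  expected <- closed_form_error(s)
  expect_lt(abs(err - expected),
            3 * sqrt(expected * (1 - expected) / m_t))
})

test_that("closed-form error matches the normal CDF and handles edges", {
  expect_equal(closed_form_error(0), 0.5)
  expect_equal(closed_form_error(4), pnorm(-1), tolerance = 1e-12)
  expect_equal(closed_form_error(9), pnorm(-1.5), tolerance = 1e-12)
  expect_error(closed_form_error(-1), "nonnegative")
  # unequal priors: agrees with numeric quadrature of min(pi_k f_k)
  pri <- c(0.3, 0.7)
  s <- 2.5
  f <- function(z) pmin(pri[1] * dnorm(z), pri[2] * dnorm(z - sqrt(s)))
  oracle <- integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(closed_form_error(s, pri), oracle, tolerance = 1e-8)
})

test_that("predictions agree with an independent reference LDA", {
  skip_if_not_installed("MASS")
  withr::with_seed(65, {
    n <- 300
    y <- rep_len(c("a", "b"), n)
    z <- matrix(rnorm(n * 2), n, 2)
    z[y == "b", ] <- z[y == "b", ] + c(2.5, 1)
    z_new <- matrix(rnorm(400), 200, 2)
  })
  ours <- predict(fit_gaussian_classifier(z, y, "lda"), z_new)
  ref <- predict(MASS::lda(z, grouping = y), z_new)$class
  # denominators differ (1/n vs 1/(n-C)) so only near-boundary points can
  # flip; demand near-perfect agreement
  expect_gte(mean(as.character(ours) == as.character(ref)), 0.99)
})

test_that("degenerate covariances are ridged or rejected", {
  z <- cbind(c(1, 1, 2, 2), c(2, 2, 4, 4), c(0, 0, 1, 1)) # d > n - C
  y <- c(0, 0, 1, 1)
  expect_warning(clf <- fit_gaussian_classifier(z, y, kind = "lda"),
                 "rank-deficient")
  expect_s3_class(clf, "gaussian_classifier")
  expect_error(predict(clf, matrix(0, 1, 4)), "dimension")
})
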