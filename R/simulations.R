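# Population specifications and seeded samplers for the canonical wide-data
# Gaussian simulation settings. Every setting stores exact population
# parameters (class priors, means, per-class variances in a diagonal frame,
# and an optional shared rotation), so Bayes error and Chernoff information
# can be computed against the truth.
#
# Covariances are Sigma_c = Q diag(vars_c) Q' -- diagonal up to a shared
# rotation -- which covers every built-in design and keeps sampling linear
# in p.

trunk_delta <- function(p, b) 2 * b / sqrt(seq_len(p))

trunk_vars <- function(p, maxvar, decay) {
  1 + (maxvar - 1) * decay^(p - seq_len(p))
}

#' Construct a Gaussian simulation setting
#'
#' Fully specified class-conditional Gaussian populations emulating the
#' standard wide-data benchmark geometries:
#'
#' * `trunk2` -- two classes, shared diagonal covariance whose variances
#'   increase strictly with the coordinate index (`1 + (maxvar-1) *
#'   decay^(p-j)`, i.e. 1 up to `maxvar` with an exponentially concentrated
#'   high-variance tail) while the mean-difference components `2b/sqrt(j)`
#'   decrease: the discriminating directions are orthogonal to the
#'   directions of maximal variance.
#' * `trunk3` -- three equiprobable classes along the trunk pattern at
#'   `-delta, 0, +delta`, the third shifted by a reversed-decay pattern so
#'   both mean-difference directions are informative.
#' * `rotated_trunk` -- `trunk2` after a seeded Haar-random rotation of all
#'   `p` dimensions (pass `Q = diag(p)` for the identity rotation).
#' * `cigars` -- stacked cigars: one high-variance coordinate (`maxvar`)
#'   carrying most of the mean difference, calibrated so the Fisher SNR
#'   equals `snr`.
#' * `cross` -- equal means, orthogonal covariances: class 0 is inflated
#'   along `e1`, class 1 along `e2` (variance `1 + spike`).
#' * `robust` -- `trunk2` plus training-set contamination: a fraction `rho`
#'   of training draws has its noise inflated by `scale` (labels kept; test
#'   data stay clean).
#' * `spherical` -- isotropic covariance with the mean difference along a
#'   seeded random unit direction, its length set so the Bayes error equals
#'   `bayes`.
#'
#' @param name One of `"trunk2"`, `"trunk3"`, `"rotated_trunk"`,
#'   `"cigars"`, `"cross"`, `"robust"`, `"spherical"`.
#' @param p Ambient dimension (`>= 2`; `>= 3` for `trunk3`).
#' @param ... Setting-specific overrides: `b` (trunk mean scale, default 3),
#'   `maxvar` (default 100), `decay` (default 0.97), `snr` (cigars, default
#'   9), `spike` (cross, default 99), `rho`/`scale` (robust, defaults
#'   0.2/10), `bayes` (spherical, default 0.02), `direction_seed`
#'   (spherical, default 1), `rotation_seed`/`Q` (rotated_trunk).
#' @return An object of class `gaussian_setting` with elements `name`, `p`,
#'   `priors`, `means` (`p x C`, ambient frame), `vars` (`p x C`, diagonal
#'   frame), `rotation` (`NULL` or orthogonal `Q`), `contamination`, `snr`
#'   (Fisher SNR for shared-covariance two-class settings), `bayes_error`
#'   (closed form where available, otherwise `NA`).
#' @export
make_setting <- function(name, p, ...) {
  name <- match.arg(name, c("trunk2", "trunk3", "rotated_trunk", "cigars",
                            "cross", "robust", "spherical"))
  p <- as.integer(p)
  if (p < 2L) stop("p must be >= 2", call. = FALSE)
  opts <- list(...)
  b <- opts$b %||% 3
  maxvar <- opts$maxvar %||% 100
  decay <- opts$decay %||% 0.97

  st <- switch(
    name,
    trunk2 = {
      delta <- trunk_delta(p, b)
      v <- trunk_vars(p, maxvar, decay)
      list(priors = c(0.5, 0.5),
           means = cbind(-delta / 2, delta / 2),
           vars = cbind(v, v))
    },
    trunk3 = {
      if (p < 3L) stop("trunk3 needs p >= 3", call. = FALSE)
      delta <- trunk_delta(p, b)
      rev_delta <- 2 * b / sqrt(p + 1 - seq_len(p))
      v <- trunk_vars(p, maxvar, decay)
      list(priors = rep(1 / 3, 3),
           means = cbind(-delta, 0 * delta, delta + rev_delta),
           vars = cbind(v, v, v))
    },
    rotated_trunk = {
      base <- make_setting("trunk2", p, b = b, maxvar = maxvar,
                           decay = decay)
      Q <- opts$Q %||% random_orthogonal(p, seed = opts$rotation_seed %||% 1L)
      if (max(abs(crossprod(Q) - diag(p))) > 1e-10) {
        stop("Q is not orthogonal", call. = FALSE)
      }
      out <- base
      out$means <- Q %*% base$means
      out$rotation <- Q
      out$name <- "rotated_trunk"
      return(finalize_setting(out))
    },
    cigars = {
      snr <- opts$snr %||% 9
      tail_sum <- if (p >= 2L) sum(1 / seq(2L, p)) else 0
      K <- sqrt(snr / (1 / maxvar + 0.01 * tail_sum))
      delta <- c(K, 0.1 * K / sqrt(seq(2L, p)))
      v <- c(maxvar, rep(1, p - 1L))
      list(priors = c(0.5, 0.5),
           means = cbind(-delta / 2, delta / 2),
           vars = cbind(v, v))
    },
    cross = {
      spike <- opts$spike %||% 99
      v0 <- rep(1, p); v0[1L] <- 1 + spike
      v1 <- rep(1, p); v1[2L] <- 1 + spike
      list(priors = c(0.5, 0.5),
           means = cbind(rep(0, p), rep(0, p)),
           vars = cbind(v0, v1))
    },
    robust = {
      base <- make_setting("trunk2", p, b = b, maxvar = maxvar,
                           decay = decay)
      out <- unclass(base)
      out$name <- "robust"
      out$contamination <- list(rho = opts$rho %||% 0.2,
                                scale = opts$scale %||% 10)
      return(finalize_setting(out))
    },
    spherical = {
      bayes <- opts$bayes %||% 0.02
      u <- with_seed(opts$direction_seed %||% 1L, stats::rnorm(p))
      u <- u / sqrt(sum(u^2))
      delta <- 2 * stats::qnorm(1 - bayes) * u
      list(priors = c(0.5, 0.5),
           means = cbind(-delta / 2, delta / 2),
           vars = cbind(rep(1, p), rep(1, p)))
    }
  )
  st$name <- name
  st$rotation <- st$rotation %||% NULL
  finalize_setting(st)
}

finalize_setting <- function(st) {
  st <- list(name = st$name, priors = unname(st$priors),
             means = unname(as.matrix(st$means)),
             vars = unname(as.matrix(st$vars)), rotation = st$rotation,
             contamination = st$contamination)
  st$p <- nrow(st$means)
  shared <- ncol(st$vars) == 2L && identical(st$vars[, 1], st$vars[, 2])
  two_class <- ncol(st$means) == 2L
  st$snr <- if (shared && two_class) {
    delta <- st$means[, 2] - st$means[, 1]
    du <- if (is.null(st$rotation)) delta else drop(crossprod(st$rotation,
                                                              delta))
    sum(du^2 / st$vars[, 1])
  } else NA_real_
  st$bayes_error <- if (!is.na(st$snr)) {
    closed_form_error(st$snr, st$priors)
  } else NA_real_
  structure(st, class = "gaussian_setting")
}

#' @export
print.gaussian_setting <- function(x, ...) {
  cat("<gaussian_setting> ", x$name, ": p=", x$p, ", C=", ncol(x$means),
      sep = "")
  if (!is.na(x$snr)) cat(", Fisher SNR=", format(x$snr, digits = 4), sep = "")
  if (!is.na(x$bayes_error)) cat(", Bayes error=",
                                 format(x$bayes_error, digits = 4), sep = "")
  if (!is.null(x$contamination)) {
    cat(", contamination rho=", x$contamination$rho, " x",
        x$contamination$scale, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Materialize a class covariance of a simulation setting
#'
#' Returns the dense `p x p` covariance `Q diag(vars_c) Q'`. Use only for
#' moderate `p` (theory checks); sampling never materializes it.
#'
#' @param setting A [make_setting()] object.
#' @param class 1-based class index.
#' @export
setting_covariance <- function(setting, class = 1L) {
  v <- setting$vars[, class]
  if (is.null(setting$rotation)) return(diag(v, setting$p))
  Q <- setting$rotation
  Q %*% (v * t(Q))
}

#' Population Gaussian pair of a two-class setting
#'
#' @param setting A two-class [make_setting()] object.
#' @return A [gaussian_pair()] with the true population parameters.
#' @export
population_pair <- function(setting) {
  if (ncol(setting$means) != 2L) {
    stop("population_pair requires a two-class setting", call. = FALSE)
  }
  gaussian_pair(setting$means[, 1], setting$means[, 2],
                setting_covariance(setting, 1L),
                setting_covariance(setting, 2L),
                priors = setting$priors)
}

#' Draw a seeded sample from a simulation setting
#'
#' Labels are drawn i.i.d. from the class priors (balanced in expectation);
#' features are exact draws from the class Gaussians. For contaminated
#' settings the contamination (noise inflated by the setting's scale,
#' labels kept) is applied to the train split only -- test data are always
#' clean.
#'
#' @param setting A [make_setting()] object.
#' @param n Number of samples (`>=` number of classes).
#' @param seed RNG seed; same seed, same dataset.
#' @param split `"train"` or `"test"`.
#' @return A [labeled_dataset()] with labels `"0", "1", ...`.
#' @export
sample_from <- function(setting, n, seed = 1L, split = c("train", "test")) {
  split <- match.arg(split)
  C <- ncol(setting$means)
  n <- as.integer(n)
  if (n < C) stop("n = ", n, " is smaller than the number of classes ", C,
                  call. = FALSE)
  with_seed(seed, {
    y <- sample.int(C, n, replace = TRUE, prob = setting$priors) - 1L
    Z <- matrix(stats::rnorm(n * setting$p), n, setting$p)
    if (!is.null(setting$contamination) && split == "train") {
      bad <- stats::runif(n) < setting$contamination$rho
      Z[bad, ] <- Z[bad, ] * setting$contamination$scale
      attr_bad <- bad
    } else {
      attr_bad <- rep(FALSE, n)
    }
    sd_mat <- sqrt(setting$vars) # p x C
    X <- Z * t(sd_mat[, y + 1L]) # scale rows by their class sd pattern
    if (!is.null(setting$rotation)) X <- X %*% t(setting$rotation)
    X <- X + t(setting$means[, y + 1L])
    out <- labeled_dataset(X, as.character(y))
    attr(out, "contaminated") <- attr_bad
    out
  })
}

#' Apply a seeded uniformly-random rotation to a setting
#'
#' Rotates means and covariances by a Haar-distributed orthogonal matrix
#' (composing with any existing rotation). The Fisher SNR is invariant.
#'
#' @param setting A [make_setting()] object.
#' @param seed Seed for the rotation draw.
#' @return The rotated `gaussian_setting`; the applied rotation is recorded
#'   in its `rotation` element.
#' @export
rotate_setting <- function(setting, seed = 1L) {
  R <- random_orthogonal(setting$p, seed = seed)
  out <- unclass(setting)
  out$means <- R %*% setting$means
  out$rotation <- if (is.null(setting$rotation)) R else R %*% setting$rotation
  finalize_setting(out)
}

#' Bayes error of a setting
#'
#' Closed form for shared-covariance two-class settings; otherwise a seeded
#' Monte-Carlo estimate using the true-parameter Bayes rule (quadratic
#' discriminant scores evaluated in the setting's diagonal frame, so the
#' cost is linear in `p`).
#'
#' @param setting A [make_setting()] object.
#' @param n_mc Monte-Carlo test size for settings without a closed form.
#' @param seed Monte-Carlo seed.
#' @export
bayes_error <- function(setting, n_mc = 1e5, seed = 1L) {
  if (!is.na(setting$bayes_error)) return(setting$bayes_error)
  test <- sample_from(setting, n_mc, seed = seed, split = "test")
  pred <- bayes_rule(setting, test$x)
  mean(pred != as.integer(as.character(test$y)))
}

# True-parameter Bayes classifications (0-based labels), computed in the
# diagonal frame.
bayes_rule <- function(setting, X) {
  C <- ncol(setting$means)
  if (!is.null(setting$rotation)) X <- X %*% setting$rotation # back-rotate
  scores <- matrix(0, nrow(X), C)
  for (k in seq_len(C)) {
    mu <- setting$means[, k]
    if (!is.null(setting$rotation)) {
      mu <- drop(crossprod(setting$rotation, mu))
    }
    v <- setting$vars[, k]
    D <- sweep(X, 2, mu)
    scores[, k] <- log(setting$priors[k]) - 0.5 * sum(log(v)) -
      0.5 * rowSums(sweep(D^2, 2, v, `/`))
  }
  max.col(scores, ties.method = "first") - 1L
}
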