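# Chernoff divergence and information between two multivariate Gaussians:
# the theoretical yardstick for embedding quality, since the Chernoff
# information is the exponential decay rate of the Bayes error.

#' Bundle two Gaussian distributions
#'
#' @param mu0,mu1 Mean vectors (length `p`).
#' @param sigma0,sigma1 Covariance matrices (`p x p`, symmetric positive
#'   definite).
#' @param priors Two class priors (recorded; the Chernoff functional itself
#'   does not use them).
#' @return An object of class `gaussian_pair`.
#' @export
gaussian_pair <- function(mu0, mu1, sigma0, sigma1, priors = c(0.5, 0.5)) {
  mu0 <- as.numeric(mu0)
  mu1 <- as.numeric(mu1)
  p <- length(mu0)
  if (length(mu1) != p) stop("mean length mismatch", call. = FALSE)
  if (p == 1L) {
    sigma0 <- matrix(sigma0, 1, 1)
    sigma1 <- matrix(sigma1, 1, 1)
  }
  for (S in list(sigma0, sigma1)) {
    if (!is_square_symmetric(S) || nrow(S) != p) {
      stop("covariances must be p x p symmetric matrices", call. = FALSE)
    }
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) stop("covariance is not positive definite", call. = FALSE)
  }
  structure(list(mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
                 priors = priors, p = p),
            class = "gaussian_pair")
}

#' Push a Gaussian pair through a linear embedding
#'
#' Means map to `W' mu`, covariances to `W' Sigma W`.
#'
#' @param pair A [gaussian_pair()].
#' @param W `p x d` projection matrix of full column rank.
#' @return The embedded `gaussian_pair` in `d` dimensions.
#' @export
project_gaussians <- function(pair, W) {
  stopifnot(inherits(pair, "gaussian_pair"))
  if (inherits(W, "projection_model")) W <- W$W
  W <- as.matrix(W)
  if (nrow(W) != pair$p) stop("W must have p rows", call. = FALSE)
  if (qr(W)$rank < ncol(W)) stop("W is rank deficient", call. = FALSE)
  gaussian_pair(drop(crossprod(W, pair$mu0)), drop(crossprod(W, pair$mu1)),
                crossprod(W, pair$sigma0 %*% W),
                crossprod(W, pair$sigma1 %*% W),
                priors = pair$priors)
}

#' Chernoff divergence between two Gaussians at exponent t
#'
#' `C(t) = t(1-t)/2 * delta' Sigma_t^-1 delta
#'        + 1/2 * log( det Sigma_t / (det Sigma0^(1-t) det Sigma1^t) )`
#' with `delta = mu1 - mu0` and `Sigma_t = (1-t) Sigma0 + t Sigma1`, in
#' nats, computed through Cholesky log-determinants.
#'
#' @param pair A [gaussian_pair()].
#' @param t Exponent in the open interval `(0, 1)`.
#' @return Divergence in nats (nonnegative).
#' @export
chernoff_divergence <- function(pair, t) {
  stopifnot(inherits(pair, "gaussian_pair"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t >= 1) {
    stop("t must lie strictly inside (0, 1)", call. = FALSE)
  }
  St <- (1 - t) * pair$sigma0 + t * pair$sigma1
  R <- tryCatch(chol(St), error = function(e)
    stop("interpolated covariance not positive definite", call. = FALSE))
  delta <- pair$mu1 - pair$mu0
  w <- backsolve(R, delta, transpose = TRUE)
  quad <- sum(w^2)
  ld_t <- 2 * sum(log(diag(R)))
  ld0 <- log_det_chol(pair$sigma0)
  ld1 <- log_det_chol(pair$sigma1)
  t * (1 - t) / 2 * quad + 0.5 * (ld_t - (1 - t) * ld0 - t * ld1)
}

#' Chernoff information between two Gaussians
#'
#' Maximizes the Chernoff divergence over the exponent `t` in `(0, 1)` by a
#' coarse grid bracket followed by derivative-free scalar optimization
#' (tolerance `1e-10` in `t`). For equal covariances the optimum is
#' `t* = 1/2` with value `delta' Sigma^-1 delta / 8`.
#'
#' @param pair A [gaussian_pair()].
#' @return An object of class `chernoff_result`: `t_star` and `value`
#'   (nats).
#' @export
chernoff_information <- function(pair) {
  stopifnot(inherits(pair, "gaussian_pair"))
  f <- function(t) chernoff_divergence(pair, t)
  # coarse scan guards against the (rare) multimodal C(t)
  grid <- seq(0.005, 0.995, length.out = 199L)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- if (i == 1L) 1e-9 else grid[i - 1L]
  hi <- if (i == length(grid)) 1 - 1e-9 else grid[i + 1L]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  value <- max(opt$objective, 0)
  if (value < 1e-14) value <- max(0, value)
  structure(list(t_star = opt$maximum, value = value),
            class = "chernoff_result")
}

#' @export
print.chernoff_result <- function(x, ...) {
  cat("<chernoff_result> value=", format(x$value), " nats at t*=",
      format(x$t_star), "\n", sep = "")
  invisible(x)
}
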