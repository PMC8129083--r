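#' Class-conditional moment estimates
#'
#' Computes per-class location estimates (sample means, or coordinate-wise
#' medians for the robust variant), class priors, and the class-centered
#' matrix in which each sample has its own class location subtracted. The
#' class-centered covariance is `crossprod(centered)/n` conceptually but is
#' never materialized here: downstream eigenvector computations factorize the
#' centered matrix directly, which keeps the cost linear in `p`.
#'
#' @param data A [labeled_dataset()].
#' @param location Location estimator: `"mean"` or `"median"`
#'   (coordinate-wise).
#' @return An object of class `class_moments`: `priors` (named numeric),
#'   `locations` (`p x C` matrix, one column per class), `pooled_mean`,
#'   `centered` (`n x p` class-centered matrix), `class_index`, `location`.
#' @examples
#' d <- labeled_dataset(rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2)),
#'                      c("a", "a", "b", "b"))
#' m <- class_moments(d, location = "mean")
#' m$locations
#' @export
class_moments <- function(data, location = c("median", "mean")) {
  assert_dataset(data)
  location <- match.arg(location)
  C <- n_classes(data)
  p <- data$p
  locs <- matrix(0, p, C, dimnames = list(NULL, data$classes))
  centered <- data$x
  for (k in seq_len(C)) {
    rows <- data$class_index[[k]]
    xk <- data$x[rows, , drop = FALSE]
    locs[, k] <- if (location == "mean") {
      colMeans(xk)
    } else {
      apply(xk, 2, stats::median)
    }
    centered[rows, ] <- sweep(xk, 2, locs[, k])
  }
  priors <- vapply(data$class_index, length, integer(1)) / data$n
  structure(
    list(priors = priors, locations = locs,
         pooled_mean = colMeans(data$x), centered = centered,
         class_index = data$class_index, location = location,
         classes = data$classes, n = data$n, p = p),
    class = "class_moments"
  )
}

#' Class-centered covariance matrix
#'
#' Materializes the `p x p` class-centered covariance
#' `crossprod(centered)/n` (maximum-likelihood denominator). Intended for
#' small `p` only; the fitting routines never call it.
#'
#' @param moments A [class_moments()] object.
#' @return A `p x p` symmetric positive semidefinite matrix.
#' @export
class_centered_covariance <- function(moments) {
  crossprod(moments$centered) / moments$n
}

#' Mean-difference basis
#'
#' The first-moment block of every XOX projection. For two classes this is
#' the single unit vector along `mu_1 - mu_0`. For `C > 2` classes the
#' columns are the top `C - 1` left singular vectors of the prior-weighted
#' location-deviation matrix with columns `sqrt(pi_c) * (mu_c - mu_bar)`,
#' where `mu_bar` is the prior-weighted average location; this reduces to the
#' two-class difference and is invariant to class order. Columns are
#' unit-norm and ordered by singular value.
#'
#' @param moments A [class_moments()] object.
#' @return A `p x (C - 1)` matrix. The singular values of the deviation
#'   matrix are attached as attribute `"singular_values"`; zero values flag
#'   degenerate (e.g. collinear-mean) directions.
#' @export
delta_basis <- function(moments) {
  locs <- moments$locations
  C <- ncol(locs)
  if (max(abs(locs - locs[, 1])) == 0) {
    stop("all class locations are identical; no mean-difference direction",
         call. = FALSE)
  }
  if (C == 2L) {
    d <- locs[, 2] - locs[, 1]
    nrm <- sqrt(sum(d^2))
    out <- matrix(d / nrm, ncol = 1)
    attr(out, "singular_values") <- nrm
    return(out)
  }
  mu_bar <- drop(locs %*% moments$priors)
  dev <- sweep(locs, 1, mu_bar) # p x C
  dev <- sweep(dev, 2, sqrt(moments$priors), `*`)
  sv <- svd(dev, nu = min(nrow(dev), C), nv = 0)
  U <- fix_signs(sv$u[, seq_len(C - 1L), drop = FALSE])
  attr(U, "singular_values") <- sv$d[seq_len(C - 1L)]
  U
}
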