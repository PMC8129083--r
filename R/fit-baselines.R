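# Baseline embeddings: PCA, random projections, CCA, PLS.

#' Principal components projection
#'
#' Top `d` right singular vectors of the pooled-mean-centered feature
#' matrix, i.e. the top eigenvectors of the pooled sample covariance. Class
#' labels are ignored.
#'
#' @inheritParams fit_lol
#' @param x Feature matrix, data frame, or [labeled_dataset()].
#' @param y Labels; only used to build a dataset when `x` is a bare matrix,
#'   never by the fit itself. May be `NULL`.
#' @export
fit_pca <- function(x, y = NULL, d, solver = c("exact", "randomized"),
                    seed = 1L) {
  solver <- match.arg(solver)
  X <- if (inherits(x, "labeled_dataset")) x$x else if (is.data.frame(x))
    as.matrix(x) else x
  n <- nrow(X)
  p <- ncol(X)
  d <- as.integer(d)
  if (d < 1L || d > min(n - 1L, p)) {
    stop("d must be in [1, min(n-1, p)] = [1, ", min(n - 1L, p), "]",
         call. = FALSE)
  }
  Xc <- sweep(X, 2, colMeans(X))
  V <- if (solver == "exact") {
    exact_right_vectors(Xc)$v[, seq_len(d), drop = FALSE]
  } else {
    randomized_right_vectors(Xc, d, seed = seed)$v
  }
  new_projection_model(fix_signs(V), rep("pca", d), "pca",
                       fit_meta = list(solver = solver, seed = seed, d = d))
}

#' Random projection baseline
#'
#' A seeded sparse sign matrix with entries in `{-1, 0, +1}` scaled to unit
#' expected column norm. `sparsity = 1/3` is the classic sparse projection;
#' the very sparse default `1/sqrt(p)` matches the fast LFL block.
#'
#' @param p Ambient dimension.
#' @param d Embedding dimension, `d <= p`.
#' @param sparsity Nonzero probability in `(0, 1]`; default `1/sqrt(p)`.
#' @param seed RNG seed; the same seed always yields the same matrix.
#' @export
fit_rp <- function(p, d, sparsity = NULL, seed = 1L) {
  p <- as.integer(p)
  d <- as.integer(d)
  if (d > p) stop("d = ", d, " exceeds p = ", p, call. = FALSE)
  spars <- sparsity %||% (1 / sqrt(p))
  W <- rp_columns(p, d, spars, seed = seed)
  new_projection_model(W, rep("rp", d), "rp",
                       fit_meta = list(sparsity = spars, seed = seed, d = d))
}

#' Canonical correlation projection against label indicators
#'
#' Two-view CCA between the features and the class-indicator matrix, solved
#' regularization-free through the pseudo-inverse of the pooled-centered
#' feature matrix (thin SVD). At most `C - 1` directions exist. When
#' `p >= n` this exhibits maximal data piling: every training sample of a
#' class is projected onto the same point.
#'
#' @inheritParams fit_lol
#' @export
fit_cca <- function(x, y = NULL, d) {
  data <- as_dataset(x, y)
  C <- n_classes(data)
  d <- as.integer(d)
  if (d > C - 1L) {
    stop("d = ", d, " exceeds the label-indicator rank C - 1 = ", C - 1L,
         call. = FALSE)
  }
  X <- data$x
  Xc <- sweep(X, 2, colMeans(X))
  Y <- stats::model.matrix(~ y - 1, data = list(y = data$y))
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  if (r == 0L) stop("feature matrix is constant; CCA undefined",
                    call. = FALSE)
  U <- sv$u[, seq_len(r), drop = FALSE]
  Dinv <- 1 / sv$d[seq_len(r)]
  Tm <- crossprod(U, Yc) # r x C
  tsv <- svd(Tm, nu = min(r, ncol(Tm)), nv = 0)
  k <- min(d, ncol(tsv$u))
  A <- sv$v[, seq_len(r), drop = FALSE] %*%
    (Dinv * tsv$u[, seq_len(k), drop = FALSE])
  W <- fix_signs(unit_scale(A))
  new_projection_model(W, rep("cca", k), "cca",
                       fit_meta = list(d = k, classes = data$classes))
}

#' Partial least squares projection
#'
#' NIPALS-style deflation: each round takes the dominant left singular
#' vector of the cross-covariance between the (deflated) features and the
#' centered class-indicator matrix, then deflates the features by the
#' extracted score. Weight vectors across rounds are orthogonal.
#'
#' @inheritParams fit_lol
#' @export
fit_pls <- function(x, y = NULL, d) {
  data <- as_dataset(x, y)
  X <- data$x
  n <- data$n
  p <- data$p
  d <- as.integer(d)
  if (d > min(n - 1L, p)) {
    stop("d must be at most min(n-1, p) = ", min(n - 1L, p), call. = FALSE)
  }
  Xd <- sweep(X, 2, colMeans(X))
  Y <- stats::model.matrix(~ y - 1, data = list(y = data$y))
  Yc <- sweep(Y, 2, colMeans(Y))
  W <- matrix(0, p, d)
  for (j in seq_len(d)) {
    Cxy <- crossprod(Xd, Yc) # p x C
    cn <- sqrt(sum(Cxy^2))
    if (cn < 1e-12) {
      stop("cross-covariance with the labels is zero at component ", j,
           call. = FALSE)
    }
    w <- svd(Cxy, nu = 1L, nv = 0L)$u[, 1L]
    W[, j] <- w
    t_sc <- Xd %*% w
    denom <- drop(crossprod(t_sc))
    Xd <- Xd - t_sc %*% (crossprod(t_sc, Xd) / denom)
  }
  W <- fix_signs(W)
  new_projection_model(W, rep("pls", d), "pls",
                       fit_meta = list(d = d, classes = data$classes))
}
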