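# Shared fixtures and oracle helpers. All fixtures are built in code.

# The 4-point hand-checkable dataset: class 0 at x=0, class 1 at x=4, both
# classes split symmetrically in the second coordinate.
four_point_data <- function() {
  labeled_dataset(rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2)),
                  c(0, 0, 1, 1))
}

# Random Gaussian dataset with class-dependent mean shift.
rand_dataset <- function(n, p, C = 2, seed = 1, shift = 2) {
  withr::with_seed(seed, {
    y <- rep_len(seq_len(C) - 1L, n)
    x <- matrix(rnorm(n * p), n, p)
    for (k in seq_len(C) - 1L) {
      mu <- rnorm(p) / sqrt(p) * shift * k
      x[y == k, ] <- sweep(x[y == k, , drop = FALSE], 2, -mu)
    }
    labeled_dataset(x, y)
  })
}

# Flip column signs of W to match ref, then return max abs difference.
max_col_diff_aligned <- function(W, ref) {
  stopifnot(ncol(W) == ncol(ref))
  for (j in seq_len(ncol(W))) {
    if (sum(W[, j] * ref[, j]) < 0) W[, j] <- -W[, j]
  }
  max(abs(W - ref))
}

# Independent dense oracle: top-d eigenvectors of an explicitly materialized
# covariance via eigen(); never uses the package's factorization path.
eigvec_oracle <- function(S, d) {
  eigen(S, symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
}

# Class-centered covariance built from scratch (per-class mean subtraction,
# 1/n denominator), independent of class_moments().
centered_cov_oracle <- function(x, y) {
  n <- nrow(x)
  M <- x
  for (cl in unique(y)) {
    rows <- which(y == cl)
    M[rows, ] <- sweep(x[rows, , drop = FALSE], 2,
                       colMeans(x[rows, , drop = FALSE]))
  }
  crossprod(M) / n
}

# Misclassification of embed + Gaussian classifier on held-out data.
embed_error <- function(model, clf_kind, train, test) {
  z_tr <- transform_data(model, train$x)
  clf <- fit_gaussian_classifier(z_tr, train$y, kind = clf_kind)
  pred <- predict(clf, transform_data(model, test$x))
  mean(as.character(pred) != as.character(test$y))
}
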