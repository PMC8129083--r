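# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic sign convention for eigen/singular vector columns: the entry
# with the largest absolute value is made positive; ties break to the lowest
# row index (which.max takes the first maximum).
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

# Align the column signs of W to those of a reference matrix (test helper
# semantics, but also used when comparing solver outputs).
align_signs <- function(W, ref) {
  for (j in seq_len(ncol(W))) {
    if (sum(W[, j] * ref[, j]) < 0) W[, j] <- -W[, j]
  }
  W
}

unit_scale <- function(W) {
  nrm <- sqrt(colSums(W^2))
  if (any(nrm == 0)) stop("cannot normalize a zero column", call. = FALSE)
  sweep(W, 2, nrm, `/`)
}

# Haar-distributed random orthogonal matrix: QR of a standard normal matrix
# with the diagonal of R sign-fixed so the distribution is exactly uniform.
random_orthogonal <- function(p, seed = NULL) {
  with_seed(seed, {
    G <- matrix(stats::rnorm(p * p), p, p)
    dec <- qr(G)
    Q <- qr.Q(dec)
    d <- sign(diag(qr.R(dec)))
    d[d == 0] <- 1
    sweep(Q, 2, d, `*`)
  })
}

# Top-q right singular vectors of M (n x p) by a seeded randomized
# range-finder with oversampling and power iterations. Never forms p x p.
randomized_right_vectors <- function(M, q, oversample = 10L, power_iter = 2L,
                                     seed = NULL) {
  n <- nrow(M)
  p <- ncol(M)
  k <- min(q + oversample, n, p)
  with_seed(seed, {
    G <- matrix(stats::rnorm(n * k), n, k)
    Z <- crossprod(M, G) # p x k
    for (i in seq_len(power_iter)) {
      Z <- qr.Q(qr(Z))
      Z <- crossprod(M, M %*% Z)
    }
    Q <- qr.Q(qr(Z)) # p x k, orthonormal basis for the row space of M
    B <- M %*% Q # n x k
    sv <- svd(B, nu = 0, nv = k)
    V <- Q %*% sv$v
    list(v = V[, seq_len(q), drop = FALSE], d = sv$d[seq_len(q)])
  })
}

# Exact thin SVD right singular vectors of M. The full thin factorization is
# always computed (and then subset), so results are bit-identical no matter
# how many columns the caller keeps -- this is what makes truncation of a
# fitted model equal a refit.
exact_right_vectors <- function(M) {
  sv <- svd(M, nu = 0, nv = min(dim(M)))
  list(v = sv$v, d = sv$d[seq_len(min(dim(M)))])
}

log_det_chol <- function(S) {
  2 * sum(log(diag(chol(S))))
}

is_square_symmetric <- function(S, tol = 1e-8) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    max(abs(S - t(S))) <= tol * max(1, max(abs(S)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
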