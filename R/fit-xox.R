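# The XOX family: supervised projections built by concatenating
# class-conditional first-moment directions with a factorization of the
# class-centered second moment.

# Very sparse random projection columns: entries in {-1, 0, +1} scaled so the
# expected squared column norm is 1; nonzero probability `sparsity`. Columns
# are drawn sequentially from a single seeded stream (a fixed p draws per
# column), so the first d' columns of a d-column draw equal a d'-column draw
# with the same seed -- the nesting property holds for LFL too.
rp_columns <- function(p, d, sparsity, seed = NULL) {
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity > 1) {
    stop("sparsity must be in (0, 1]", call. = FALSE)
  }
  val <- 1 / sqrt(p * sparsity)
  with_seed(seed, {
    W <- matrix(0, p, d)
    for (j in seq_len(d)) {
      u <- stats::runif(p)
      col <- numeric(p)
      col[u < sparsity / 2] <- -val
      col[u > 1 - sparsity / 2] <- val
      W[, j] <- col
    }
    W
  })
}

# Shared engine behind fit_lol / fit_qoq / fit_lfl / fit_rrlda.
xox_engine <- function(data, d, location, second_moment, solver, sparsity,
                       seed, orthogonalize, method, include_delta = TRUE) {
  assert_dataset(data)
  d <- as.integer(d)
  p <- data$p
  n <- data$n
  C <- n_classes(data)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (d > p) stop("d = ", d, " exceeds feature dimension p = ", p,
                  call. = FALSE)
  moments <- class_moments(data, location)

  n_delta <- if (include_delta) min(C - 1L, d) else 0L
  q <- d - n_delta
  blocks <- list()
  kinds <- character(0)
  if (n_delta > 0L) {
    D <- delta_basis(moments)[, seq_len(n_delta), drop = FALSE]
    blocks <- c(blocks, list(D))
    kinds <- c(kinds, rep("mean_diff", n_delta))
  }
  if (q > 0L) {
    if (second_moment == "shared_eig") {
      if (q > min(n, p)) {
        stop("requested ", q, " eigenvector columns but the centered matrix",
             " has rank at most ", min(n, p), call. = FALSE)
      }
      M <- moments$centered
      vecs <- if (solver == "exact") {
        ex <- exact_right_vectors(M)
        ex$v[, seq_len(q), drop = FALSE]
      } else {
        randomized_right_vectors(M, q, seed = seed)$v
      }
      blocks <- c(blocks, list(fix_signs(vecs)))
      kinds <- c(kinds, rep("shared_eig", q))
    } else if (second_moment == "per_class_eig") {
      per <- vector("list", C)
      for (k in seq_len(C)) {
        rows <- moments$class_index[[k]]
        Mk <- moments$centered[rows, , drop = FALSE]
        r_k <- min(length(rows), p)
        if (solver == "exact") {
          ex <- exact_right_vectors(Mk)
          per[[k]] <- list(v = fix_signs(ex$v),
                           sv = ex$d / sqrt(length(rows)))
        } else {
          r_use <- min(q, r_k)
          rz <- randomized_right_vectors(Mk, r_use, seed = seed + k)
          per[[k]] <- list(v = fix_signs(rz$v), sv = rz$d / sqrt(length(rows)))
        }
      }
      sv_all <- unlist(lapply(per, `[[`, "sv"))
      cls_all <- rep(seq_len(C), vapply(per, function(z) length(z$sv),
                                        integer(1)))
      pos_all <- unlist(lapply(per, function(z) seq_along(z$sv)))
      ord <- order(-sv_all) # stable: ties keep original (class, index) order
      if (q > length(ord)) {
        stop("requested ", q, " eigenvector columns but only ", length(ord),
             " per-class directions are available", call. = FALSE)
      }
      take <- ord[seq_len(q)]
      V <- vapply(take, function(i) per[[cls_all[i]]]$v[, pos_all[i]],
                  numeric(p))
      V <- matrix(V, nrow = p)
      blocks <- c(blocks, list(V))
      kinds <- c(kinds, paste0("class", cls_all[take] - 1L, "_eig"))
    } else if (second_moment == "sparse_rp") {
      spars <- sparsity %||% (1 / sqrt(p))
      blocks <- c(blocks, list(rp_columns(p, q, spars, seed = seed)))
      kinds <- c(kinds, rep("sparse_rp", q))
    } else {
      stop("unknown second_moment: ", second_moment, call. = FALSE)
    }
  }
  W <- do.call(cbind, blocks)
  # unit-normalize every non-RP column; RP columns keep their expected-norm
  # scaling
  non_rp <- kinds != "sparse_rp"
  if (any(non_rp)) {
    W[, non_rp] <- unit_scale(W[, non_rp, drop = FALSE])
  }
  if (orthogonalize && ncol(W) > 1L) {
    qr_dec <- qr(W)
    if (qr_dec$rank < ncol(W)) {
      stop("columns are collinear; cannot orthogonalize", call. = FALSE)
    }
    Wq <- qr.Q(qr_dec)
    # keep each column's orientation aligned with the original
    W <- align_signs(Wq, W)
  }
  new_projection_model(
    W, kinds, method,
    fit_meta = list(location = location, solver = solver, seed = seed,
                    sparsity = if (second_moment == "sparse_rp")
                      (sparsity %||% (1 / sqrt(p))) else NULL,
                    classes = data$classes, d = d,
                    orthogonalized = orthogonalize)
  )
}

#' Linear Optimal Low-rank projection (LOL)
#'
#' Concatenates the `C - 1` class mean-difference directions with the top
#' `d - (C - 1)` eigenvectors of the class-centered covariance (computed as
#' right singular vectors of the class-centered matrix, so a `p x p`
#' covariance is never formed). The default location estimator is the
#' coordinate-wise class median, the robust variant reported to behave well
#' with and without outliers; `location = "mean"` gives the classical
#' construction. Requesting `d <= C - 1` yields a means-only projection.
#'
#' @param x Feature matrix (`n x p`), data frame, or a [labeled_dataset()].
#' @param y Class labels (ignored when `x` is already a labeled dataset).
#' @param d Embedding dimension, `1 <= d <= p`.
#' @param location Class location estimator, `"median"` (default) or
#'   `"mean"`.
#' @param solver `"exact"` (thin SVD) or `"randomized"` (seeded range-finder
#'   with oversampling 10 and 2 power iterations; approximate).
#' @param seed Seed for the randomized solver.
#' @param orthogonalize If `TRUE`, apply Gram-Schmidt to the concatenated
#'   columns. Off by default: the construction concatenates, it does not
#'   orthogonalize.
#' @return A `projection_model` with `column_kind` recording the provenance
#'   of every column (`mean_diff` columns first).
#' @examples
#' d4 <- labeled_dataset(rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2)),
#'                       c(0, 0, 1, 1))
#' fit_lol(d4, d = 2, location = "mean")$W
#' @export
fit_lol <- function(x, y = NULL, d, location = c("median", "mean"),
                    solver = c("exact", "randomized"), seed = 1L,
                    orthogonalize = FALSE) {
  data <- as_dataset(x, y)
  xox_engine(data, d, match.arg(location), "shared_eig", match.arg(solver),
             NULL, seed, orthogonalize, method = "lol")
}

#' Quadratic Optimal QDA projection (QOQ)
#'
#' XOX variant for classes with different covariances: the eigenvectors are
#' computed separately for each class's centered matrix, pooled, sorted
#' globally by their singular values (no per-class quota), and the top
#' `d - (C - 1)` are concatenated after the mean-difference block. Pair with
#' a QDA classifier downstream.
#'
#' @inheritParams fit_lol
#' @return A `projection_model`; eigenvector columns are tagged
#'   `class<k>_eig` by originating class.
#' @export
fit_qoq <- function(x, y = NULL, d, location = c("median", "mean"),
                    solver = c("exact", "randomized"), seed = 1L,
                    orthogonalize = FALSE) {
  data <- as_dataset(x, y)
  xox_engine(data, d, match.arg(location), "per_class_eig", match.arg(solver),
             NULL, seed, orthogonalize, method = "qoq")
}

#' Low-rank Fast Linear projection (LFL)
#'
#' Fast LOL variant replacing the eigenvector block with seeded very sparse
#' random projection columns (nonzero probability `sparsity`, default
#' `1/sqrt(p)`), trading a little accuracy for an order-of-magnitude cheaper
#' second-moment block.
#'
#' @inheritParams fit_lol
#' @param sparsity Nonzero probability of the random projection entries, in
#'   `(0, 1]`; default `1/sqrt(p)`.
#' @export
fit_lfl <- function(x, y = NULL, d, location = c("median", "mean"),
                    sparsity = NULL, seed = 1L) {
  data <- as_dataset(x, y)
  xox_engine(data, d, match.arg(location), "sparse_rp", "exact", sparsity,
             seed, FALSE, method = "lfl")
}

#' Reduced-rank LDA projection (rrLDA)
#'
#' Projects onto the top `d` eigenvectors of the class-centered covariance
#' only -- no mean-difference column. Invariant to per-class mean shifts,
#' which is exactly why it is blind to settings where the discriminating
#' information lives in the means.
#'
#' @inheritParams fit_lol
#' @export
fit_rrlda <- function(x, y = NULL, d, location = c("mean", "median"),
                      solver = c("exact", "randomized"), seed = 1L) {
  data <- as_dataset(x, y)
  xox_engine(data, d, match.arg(location), "shared_eig", match.arg(solver),
             NULL, seed, FALSE, method = "rrlda", include_delta = FALSE)
}

# Accepts (matrix, labels) or an existing labeled_dataset.
as_dataset <- function(x, y) {
  if (inherits(x, "labeled_dataset")) return(x)
  if (is.null(y)) stop("labels y are required", call. = FALSE)
  labeled_dataset(x, y)
}
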