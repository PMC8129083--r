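# Gaussian discriminant classifiers on embedded data.

#' Fit a Gaussian discriminant classifier (LDA or QDA)
#'
#' Plug-in estimates: class priors from training proportions, class means,
#' and either a pooled class-centered covariance (LDA) or per-class
#' covariances (QDA), all with maximum-likelihood `1/n` denominators. A
#' ridge `1e-8 * trace(S)/d` is always added because embedded dimensions can
#' be collinear when `d` approaches `n`.
#'
#' @param z `n x d` matrix of embedded training samples (or a vector for
#'   `d = 1`).
#' @param y Training labels; classes are coded in order of first appearance
#'   (or factor level order when a factor is supplied).
#' @param kind `"lda"` (shared covariance) or `"qda"` (per-class).
#' @return An object of class `gaussian_classifier`.
#' @export
fit_gaussian_classifier <- function(z, y, kind = c("lda", "qda")) {
  kind <- match.arg(kind)
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  n <- nrow(z)
  d <- ncol(z)
  yf <- if (is.factor(y)) droplevels(y) else
    factor(as.character(y), levels = unique(as.character(y)))
  C <- nlevels(yf)
  if (length(yf) != n) stop("label/row mismatch", call. = FALSE)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (d > n - C) {
    warning("d > n - C: covariance estimate is rank-deficient; ",
            "relying on the ridge", call. = FALSE)
  }
  idx <- split(seq_len(n), yf)
  priors <- vapply(idx, length, integer(1)) / n
  means <- vapply(idx, function(r) colMeans(z[r, , drop = FALSE]),
                  numeric(d))
  means <- matrix(means, nrow = d)
  centered <- z
  for (k in seq_len(C)) {
    centered[idx[[k]], ] <- sweep(z[idx[[k]], , drop = FALSE], 2, means[, k])
  }
  ridge_of <- function(S) 1e-8 * sum(diag(S)) / d
  if (kind == "lda") {
    S <- crossprod(centered) / n
    eps <- ridge_of(S)
    if (eps == 0) eps <- 1e-12
    S <- S + diag(eps, d)
    cov <- S
    chol_ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!chol_ok) stop("singular pooled covariance after ridge",
                       call. = FALSE)
  } else {
    cov <- vector("list", C)
    for (k in seq_len(C)) {
      Sk <- crossprod(centered[idx[[k]], , drop = FALSE]) / length(idx[[k]])
      eps <- ridge_of(Sk)
      if (eps == 0) eps <- 1e-12
      Sk <- Sk + diag(eps, d)
      ok <- tryCatch({ chol(Sk); TRUE }, error = function(e) FALSE)
      if (!ok) stop("singular covariance for class ", levels(yf)[k],
                    " after ridge", call. = FALSE)
      cov[[k]] <- Sk
    }
  }
  structure(
    list(kind = kind, priors = priors, means = means, cov = cov,
         classes = levels(yf), d = d),
    class = "gaussian_classifier"
  )
}

#' @export
print.gaussian_classifier <- function(x, ...) {
  cat("<gaussian_classifier> ", toupper(x$kind), ", d=", x$d, ", classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict class labels with a Gaussian discriminant classifier
#'
#' Assigns each sample to the class maximizing `log prior + log density`.
#' Exact ties break deterministically to the lower class index.
#'
#' @param object A [fit_gaussian_classifier()] result.
#' @param newdata `n x d` matrix of embedded samples.
#' @param ... Unused.
#' @return Factor of predicted labels with the training class levels.
#' @export
predict.gaussian_classifier <- function(object, newdata, ...) {
  z <- as.matrix(newdata)
  if (ncol(z) != object$d) {
    stop("dimension error: data has ", ncol(z), " columns, classifier ",
         "expects ", object$d, call. = FALSE)
  }
  C <- length(object$classes)
  scores <- matrix(0, nrow(z), C)
  for (k in seq_len(C)) {
    S <- if (object$kind == "lda") object$cov else object$cov[[k]]
    R <- chol(S)
    diff <- sweep(z, 2, object$means[, k])
    w <- backsolve(R, t(diff), transpose = TRUE) # R^-T diff^T
    maha <- colSums(w^2)
    scores[, k] <- log(object$priors[k]) - 0.5 * maha -
      sum(log(diag(R)))
  }
  pick <- max.col(scores, ties.method = "first")
  factor(object$classes[pick], levels = object$classes)
}

#' Closed-form error of the equal-covariance two-class Gaussian problem
#'
#' For two Gaussian classes sharing a covariance, the Bayes rule is Fisher's
#' linear discriminant and its error depends on the data only through the
#' Fisher signal-to-noise ratio `s = delta' Sigma^-1 delta`. With equal
#' priors the error is `pnorm(-sqrt(s)/2)`; with unequal priors the
#' log-prior-ratio shifts the threshold.
#'
#' @param s Fisher SNR, `s >= 0`.
#' @param priors Two class priors summing to 1.
#' @return The Bayes misclassification rate.
#' @examples
#' closed_form_error(4) # pnorm(-1)
#' @export
closed_form_error <- function(s, priors = c(0.5, 0.5)) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0) {
    stop("s must be a single nonnegative number", call. = FALSE)
  }
  if (length(priors) != 2L || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-8) {
    stop("priors must be two nonnegative numbers summing to 1",
         call. = FALSE)
  }
  if (s == 0) {
    return(if (abs(priors[1] - priors[2]) < 1e-15) 0.5 else min(priors))
  }
  delta <- sqrt(s)
  shift <- log(priors[2] / priors[1]) / delta
  tau <- delta / 2 - shift # boundary in the class-0 frame N(0,1) vs N(delta,1)
  priors[1] * stats::pnorm(tau, lower.tail = FALSE) +
    priors[2] * stats::pnorm(tau - delta)
}
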