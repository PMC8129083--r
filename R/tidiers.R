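# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a projection model
#'
#' One row per projection column with its provenance and norm.
#'
#' @param x A `projection_model`.
#' @param ... Unused.
#' @return A tibble with columns `column`, `kind`, `norm`.
#' @method tidy projection_model
#' @export
tidy.projection_model <- function(x, ...) {
  tibble::tibble(column = seq_len(x$d), kind = x$column_kind,
                 norm = sqrt(colSums(x$W^2)))
}

#' @rdname tidy.projection_model
#' @method glance projection_model
#' @export
glance.projection_model <- function(x, ...) {
  tibble::tibble(method = x$method, p = x$p, d = x$d,
                 location = x$fit_meta$location %||% NA_character_,
                 solver = x$fit_meta$solver %||% NA_character_,
                 seed = x$fit_meta$seed %||% NA_integer_)
}

#' Tidy a Gaussian discriminant classifier
#'
#' One row per class and embedded dimension with the class mean, plus the
#' class prior.
#'
#' @param x A `gaussian_classifier`.
#' @param ... Unused.
#' @method tidy gaussian_classifier
#' @export
tidy.gaussian_classifier <- function(x, ...) {
  tibble::tibble(
    class = rep(x$classes, each = x$d),
    dimension = rep(seq_len(x$d), times = length(x$classes)),
    mean = as.vector(x$means),
    prior = rep(unname(x$priors), each = x$d)
  )
}

#' @rdname tidy.gaussian_classifier
#' @method glance gaussian_classifier
#' @export
glance.gaussian_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, d = x$d, n_classes = length(x$classes))
}

#' Tidy cross-validation curves
#'
#' @param x An `eval_curves` object.
#' @param ... Unused.
#' @return The long per-fold tibble (`method`, `dim`, `fold`, `error`).
#' @method tidy eval_curves
#' @export
tidy.eval_curves <- function(x, ...) {
  x$curves
}

#' @rdname tidy.eval_curves
#' @method glance eval_curves
#' @export
glance.eval_curves <- function(x, ...) {
  x$selected
}
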