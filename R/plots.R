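# ggplot2 displays for benchmark results.

#' Plot misclassification versus embedding dimension
#'
#' One line per method with the selected dimension marked.
#'
#' @param object An `eval_curves` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_curves
#' @export
autoplot.eval_curves <- function(object, ...) {
  sm <- object$summary
  sel <- object$selected
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$dim, y = .data$mean_error,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = sel,
                        ggplot2::aes(x = .data$selected_dim,
                                     y = .data$mean_error),
                        shape = 1, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "embedding dimension d",
                  y = "mean cross-validated misclassification",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @export
plot.eval_curves <- function(x, ...) print(autoplot.eval_curves(x, ...))

#' Plot effect sizes relative to the reference method
#'
#' @param object An `xox_comparison` object.
#' @param ... Unused.
#' @method autoplot xox_comparison
#' @export
autoplot.xox_comparison <- function(object, ...) {
  tb <- object$table[object$table$method != object$reference, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$method, y = .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL,
                  y = paste0("kappa(", object$reference,
                             ") - kappa(method)")) +
    ggplot2::theme_minimal()
}
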