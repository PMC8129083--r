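#' Construct a labeled dataset
#'
#' Bundles an `n x p` numeric feature matrix (rows are samples, columns are
#' features) with a per-sample class label vector. Labels may be character,
#' factor, or numeric; internally classes are coded in order of first
#' appearance and the original names are retained as factor levels.
#'
#' @param x Numeric matrix or data frame of features, `n` samples by `p`
#'   features. All entries must be finite.
#' @param y Vector of `n` class labels with at least two distinct values.
#' @return An object of class `labeled_dataset` with elements `x` (matrix),
#'   `y` (factor with levels in first-appearance order), `n`, `p`, `classes`,
#'   and `class_index` (list mapping each class to its row indices).
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' d$n
#' @export
labeled_dataset <- function(x, y) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 samples, got ", n, call. = FALSE)
  if (p < 1L) stop("need at least 1 feature", call. = FALSE)
  if (length(y) != n) {
    stop("label/row mismatch: ", length(y), " labels for ", n, " rows",
         call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% n) + 1L
    j <- ((bad[1L] - 1L) %/% n) + 1L
    stop("non-finite entry at row ", i, ", column ", j, call. = FALSE)
  }
  yf <- factor(as.character(y), levels = unique(as.character(y)))
  if (nlevels(yf) < 2L) stop("need at least 2 classes", call. = FALSE)
  idx <- split(seq_len(n), yf)
  structure(
    list(x = unname(x), y = yf, n = n, p = p,
         classes = levels(yf), class_index = idx),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", x$n, " samples x ", x$p, " features, ",
      length(x$classes), " classes\n", sep = "")
  tab <- table(x$y)
  cat("  classes:", paste0(names(tab), " (", as.integer(tab), ")",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Load a labeled feature matrix from delimited or sparse text
#'
#' Reads a dense CSV/TSV matrix (no header by default) or a MatrixMarket
#' coordinate file (densified on load), plus labels from a separate
#' single-column text file or from a column of the matrix itself.
#'
#' @param matrix_path Path to the feature matrix. Files ending in `.mtx` are
#'   parsed as MatrixMarket coordinate format; anything else as delimited
#'   text.
#' @param labels Either a path to a label file (one label per line) or a
#'   1-based column index of `matrix_path` holding the labels (dense input
#'   only).
#' @param delim Field delimiter for dense input; inferred from the file
#'   extension when `NULL` (`,` for `.csv`, tab otherwise).
#' @param header Logical; does the dense matrix file carry a header row?
#' @return A [labeled_dataset()].
#' @export
load_labeled_matrix <- function(matrix_path, labels, delim = NULL,
                                header = FALSE) {
  if (!file.exists(matrix_path)) {
    stop("matrix file not found: ", matrix_path, call. = FALSE)
  }
  sparse <- grepl("\\.mtx$", matrix_path, ignore.case = TRUE)
  if (sparse) {
    x <- as.matrix(Matrix::readMM(matrix_path))
  } else {
    if (is.null(delim)) {
      delim <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
    }
    tb <- readr::read_delim(matrix_path, delim = delim,
                            col_names = header,
                            show_col_types = FALSE, progress = FALSE,
                            trim_ws = TRUE)
    x <- as.data.frame(tb)
  }
  label_col <- NULL
  if (is.numeric(labels)) {
    if (sparse) stop("column labels are not supported for sparse input",
                     call. = FALSE)
    j <- as.integer(labels)
    if (j < 1L || j > ncol(x)) stop("label column ", j, " out of range",
                                    call. = FALSE)
    label_col <- x[[j]]
    x <- x[, -j, drop = FALSE]
  } else {
    if (!file.exists(labels)) stop("label file not found: ", labels,
                                   call. = FALSE)
    label_col <- readr::read_lines(labels, progress = FALSE)
    label_col <- label_col[nzchar(trimws(label_col))]
    label_col <- trimws(label_col)
  }
  if (is.data.frame(x)) {
    non_num <- !vapply(x, is.numeric, logical(1))
    if (any(non_num)) {
      stop("non-numeric feature column: ", which(non_num)[1L], call. = FALSE)
    }
    x <- as.matrix(x)
  }
  if (length(label_col) != nrow(x)) {
    stop("label/row mismatch: ", length(label_col), " labels for ",
         nrow(x), " rows", call. = FALSE)
  }
  labeled_dataset(x, label_col)
}

n_classes <- function(data) length(data$classes)

assert_dataset <- function(data) {
  if (!inherits(data, "labeled_dataset")) {
    stop("expected a labeled_dataset; see labeled_dataset()", call. = FALSE)
  }
  invisible(data)
}

#' Scatter the first two features of a labeled dataset
#'
#' @param object A [labeled_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot labeled_dataset
#' @export
autoplot.labeled_dataset <- function(object, ...) {
  df <- tibble::tibble(x1 = object$x[, 1],
                       x2 = if (object$p >= 2) object$x[, 2] else 0,
                       class = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "feature 1", y = "feature 2", colour = "class") +
    ggplot2::theme_minimal()
}
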