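# ProjectionModel: a p x d linear embedding with per-column provenance.

new_projection_model <- function(W, column_kind, method, fit_meta = list()) {
  W <- as.matrix(W)
  if (length(column_kind) != ncol(W)) {
    stop("column_kind must have one tag per column", call. = FALSE)
  }
  if (any(!is.finite(W))) stop("projection has non-finite entries",
                               call. = FALSE)
  structure(
    list(W = unname(W), column_kind = as.character(column_kind),
         method = method, fit_meta = fit_meta,
         p = nrow(W), d = ncol(W)),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat("<projection_model> method=", x$method, ", p=", x$p, ", d=", x$d,
      "\n  columns: ", paste(x$column_kind, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project data through a fitted embedding
#'
#' Computes `X %*% W`. No recentering is applied: any centering information
#' lives in the downstream classifier, so train and test data are mapped by
#' the identical linear map.
#'
#' @param model A `projection_model`.
#' @param x Numeric matrix (or data frame / labeled_dataset) with `p`
#'   columns.
#' @return An `n x d` numeric matrix.
#' @export
transform_data <- function(model, x) {
  stopifnot(inherits(model, "projection_model"))
  if (inherits(x, "labeled_dataset")) x <- x$x
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$p) {
    stop("dimension error: data has ", ncol(x), " columns, model expects ",
         model$p, call. = FALSE)
  }
  unname(x %*% model$W)
}

#' @param object A `projection_model`.
#' @param newdata Matrix of new samples to embed.
#' @param ... Unused.
#' @rdname transform_data
#' @export
predict.projection_model <- function(object, newdata, ...) {
  transform_data(object, newdata)
}

#' Truncate a fitted projection to fewer dimensions
#'
#' Keeps the first `d` columns. For every exact-solver method the embedding
#' dimensions are nested, so the truncation is bit-identical to refitting at
#' the smaller dimension; this is what makes dimension sweeps cheap.
#'
#' @param model A `projection_model`.
#' @param d Target dimension, at most `model$d`.
#' @return A `projection_model` with `d` columns and the same metadata.
#' @export
nested_truncate <- function(model, d) {
  stopifnot(inherits(model, "projection_model"))
  d <- as.integer(d)
  if (d > model$d) stop("cannot truncate to ", d, " > fitted ", model$d,
                        call. = FALSE)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (d == model$d) return(model)
  meta <- model$fit_meta
  meta$d <- d
  new_projection_model(model$W[, seq_len(d), drop = FALSE],
                       model$column_kind[seq_len(d)],
                       model$method, meta)
}

projection_format_version <- "xoxdr-projection-v1"

#' Serialize a projection model to a structured text file
#'
#' Writes a single diff-able text container: a version line, a JSON metadata
#' block (method, column kinds, fit metadata), then the `p x d` matrix with
#' 17 significant digits so the round trip is lossless at full double
#' precision.
#'
#' @param model A `projection_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_projection()]
#' @export
save_projection <- function(model, path) {
  stopifnot(inherits(model, "projection_model"))
  meta <- list(
    version = projection_format_version,
    method = model$method,
    p = model$p, d = model$d,
    column_kind = model$column_kind,
    fit_meta = model$fit_meta
  )
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste0("#", projection_format_version), con)
  writeLines(paste0("#meta\t", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                digits = NA)), con)
  rows <- apply(model$W, 1, function(r) paste(sprintf("%.17g", r),
                                              collapse = "\t"))
  writeLines(rows, con)
  invisible(path)
}

#' Load a projection model written by [save_projection()]
#'
#' @param path File path.
#' @return A `projection_model` equal to the saved one.
#' @export
load_projection <- function(path) {
  if (!file.exists(path)) stop("projection file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("parse error: truncated projection file",
                               call. = FALSE)
  if (lines[1L] != paste0("#", projection_format_version)) {
    stop("parse error: unsupported projection format version: ",
         sub("^#", "", lines[1L]), call. = FALSE)
  }
  if (!startsWith(lines[2L], "#meta\t")) {
    stop("parse error: missing metadata block", call. = FALSE)
  }
  meta <- tryCatch(
    jsonlite::fromJSON(sub("^#meta\t", "", lines[2L]), simplifyVector = TRUE),
    error = function(e) stop("parse error: corrupt metadata block",
                             call. = FALSE)
  )
  needed <- c("method", "p", "d", "column_kind")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0L) {
    stop("parse error: metadata missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  body <- lines[-(1:2)]
  if (length(body) != meta$p) {
    stop("parse error: expected ", meta$p, " matrix rows, found ",
         length(body), call. = FALSE)
  }
  W <- tryCatch({
    vals <- strsplit(body, "\t", fixed = TRUE)
    m <- do.call(rbind, lapply(vals, as.numeric))
    if (any(!is.finite(m)) || ncol(m) != meta$d) stop("bad matrix block")
    m
  }, error = function(e) stop("parse error: corrupt matrix block",
                              call. = FALSE),
     warning = function(e) stop("parse error: corrupt matrix block",
                                call. = FALSE))
  fit_meta <- meta$fit_meta
  if (is.null(fit_meta)) fit_meta <- list()
  new_projection_model(W, as.character(meta$column_kind), meta$method,
                       as.list(fit_meta))
}
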