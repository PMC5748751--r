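# broom-style accessors and JSON serialization for qspr_model objects.

#' Tidy a QSPR model
#'
#' One row per model term.  For OLS fits the usual standard errors,
#' t statistics and p-values are included; PLS coefficients are reported
#' without per-term inference.
#'
#' @param x A `qspr_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and `std.error`,
#'   `statistic`, `p.value` for OLS).
#' @exportS3Method generics::tidy
tidy.qspr_model <- function(x, ...) {
  terms <- c("(Intercept)", names(x$coefficients))
  est <- c(x$intercept, unname(x$coefficients))
  if (!is.null(x$coef_table)) {
    ct <- x$coef_table[terms, , drop = FALSE]
    tibble(term = terms, estimate = est,
           std.error = ct[, "Std. Error"],
           statistic = ct[, "t value"],
           p.value = ct[, "Pr(>|t|)"])
  } else {
    tibble(term = terms, estimate = est)
  }
}

#' Glance at a QSPR model
#'
#' @param x A `qspr_model`.
#' @param ... Unused.
#' @return A one-row tibble of fit statistics: `r.squared`,
#'   `adj.r.squared`, `q.squared`, `press`, `statistic` (F), `p.value`,
#'   `sigma` (SEE), `rmse`, `nobs`, `df`, `method`, `n_components`.
#' @exportS3Method generics::glance
glance.qspr_model <- function(x, ...) {
  s <- x$stats
  tibble(r.squared = s$r2, adj.r.squared = s$r2_adj, q.squared = s$q2,
         press = s$press, statistic = s$f_stat, p.value = s$p_value,
         sigma = s$see, rmse = s$rmse, nobs = s$n, df = s$k,
         method = x$method,
         n_components = x$n_components %||% NA_integer_)
}

#' Augment data with QSPR model predictions
#'
#' @param x A `qspr_model`.
#' @param data Data to augment; defaults to the training data.
#' @param ... Unused.
#' @return `data` with `.fitted` appended, and `.resid` where the response
#'   column is present.
#' @exportS3Method generics::augment
augment.qspr_model <- function(x, data = x$data, ...) {
  out <- as_tibble(data)
  out$.fitted <- predict(x, out)
  if (x$response %in% names(out)) {
    out$.resid <- out[[x$response]] - out$.fitted
  }
  out
}

#' Serialize a QSPR model to and from JSON
#'
#' Stores the intercept, coefficients, method, component count, scaling,
#' training ids and fit statistics; a deserialized model predicts
#' identically to the original.
#'
#' @param model A `qspr_model`.
#' @param path JSON file path.
#' @return `qspr_model_to_json()` returns `path` invisibly;
#'   `qspr_model_from_json()` returns a `qspr_model` (without the training
#'   data table, which is not serialized).
#' @export
qspr_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "qspr_model"))
  payload <- list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    method = model$method,
    n_components = model$n_components,
    scaling = model$scaling,
    response = model$response,
    descriptors = as.list(model$descriptors),
    training_ids = model$training_ids,
    y_train_mean = model$y_train_mean,
    stats = model$stats
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname qspr_model_to_json
#' @export
qspr_model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    intercept = p$intercept,
    coefficients = unlist(p$coefficients),
    method = p$method,
    n_components = p$n_components,
    scaling = p$scaling,
    response = p$response,
    descriptors = unlist(p$descriptors),
    training_ids = p$training_ids,
    y_train_mean = p$y_train_mean,
    coef_table = NULL,
    residuals = NULL,
    data = NULL,
    stats = lapply(p$stats, function(v) v %||% NA_real_)
  ), class = "qspr_model")
}
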