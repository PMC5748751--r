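# Model validation: leave-one-out Q2, RMSE, external test-set validation,
# residual-based outlier screening.

loo_q2_core <- function(X, y, method, n_components = NULL) {
  n <- nrow(X)
  if (n < 4) {
    abort_flav("leave-one-out validation needs n >= 4",
               class = "flavperm_insufficient_data")
  }
  pred <- numeric(n)
  for (i in seq_len(n)) {
    core <- withCallingHandlers(
      tryCatch(
        fit_core(X[-i, , drop = FALSE], y[-i], method, n_components),
        flavperm_singular_error = function(e) {
          abort_flav(sprintf("leave-one-out refit is singular when fold %d is left out", i),
                     class = "flavperm_fold_error")
        }
      )
    )
    pred[i] <- core$intercept + sum(X[i, ] * core$coefficients)
  }
  press <- sum((y - pred)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  list(q2 = q2, press = press, predictions = pred)
}

#' Leave-one-out cross-validated Q2
#'
#' For each compound, refits the model on the remaining n-1 compounds and
#' predicts the held-out response.  `PRESS` is the sum of squared held-out
#' prediction errors and `q2 = 1 - PRESS / TSS` with TSS taken about the
#' full-sample mean.  A Q2 above 0.5 is the conventional reliability gate
#' for a QSPR model.
#'
#' @param data A data frame (one row per compound) or a fitted
#'   `qspr_model`, in which case its training data, method and component
#'   count are reused.
#' @param response,descriptors,method,n_components As in [qspr_fit()];
#'   ignored when `data` is a `qspr_model`.
#' @param ... Unused.
#' @return A one-row tibble: `q2`, `press`, `n`.
#' @examples
#' study <- load_study("fang2017")
#' training <- dplyr::filter(study$descriptors, split == "training")
#' loo_q2(training, "ppapp_exp", c("QC3p", "E_sol", "SlogP_V3", "vsurf_ID1"))
#' @export
loo_q2 <- function(data, ...) UseMethod("loo_q2")

#' @rdname loo_q2
#' @export
loo_q2.data.frame <- function(data, response, descriptors,
                              method = c("ols", "pls"), n_components = NULL,
                              ...) {
  method <- match.arg(method)
  check_columns(data, c(response, descriptors))
  X <- as.matrix(data[descriptors])
  y <- data[[response]]
  if (method == "pls" && is.null(n_components)) n_components <- ncol(X)
  out <- loo_q2_core(X, y, method, n_components)
  tibble(q2 = out$q2, press = out$press, n = nrow(X))
}

#' @rdname loo_q2
#' @export
loo_q2.qspr_model <- function(data, ...) {
  model <- data
  loo_q2.data.frame(model$data, model$response, model$descriptors,
                    method = model$method, n_components = model$n_components)
}

#' Root-mean-square error
#'
#' `sqrt(mean((observed - predicted)^2))`, the accuracy summary used for
#' both training-set and test-set predictions.
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return A single number on the scale of the response.
#' @examples
#' rmse(c(1, 2), c(1.3, 1.6)) # 0.3536
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    abort_flav("`observed` and `predicted` must have equal length >= 1",
               class = "flavperm_domain_error")
  }
  sqrt(mean((observed - predicted)^2))
}

#' External validation on a held-out test set
#'
#' Predictive coefficient of determination referenced to the training-set
#' mean: `r2_pred = 1 - sum((y - yhat)^2) / sum((y - mean(y_train))^2)`.
#' A constant predictor equal to the training mean scores exactly 0; a
#' perfect predictor scores 1.  Also reports the test-set RMSE.
#'
#' @param model A fitted `qspr_model`.
#' @param newdata Test-set data frame with the response and all model
#'   descriptors; at least 2 rows.
#' @param response Response column in `newdata`; defaults to the model's.
#' @return A one-row tibble: `n`, `r2_pred`, `rmse`.
#' @export
validate_external <- function(model, newdata, response = model$response) {
  stopifnot(inherits(model, "qspr_model"))
  check_columns(newdata, response, where = "newdata")
  if (nrow(newdata) < 2) {
    abort_flav("external validation needs at least 2 test compounds",
               class = "flavperm_insufficient_data")
  }
  y <- newdata[[response]]
  yhat <- predict(model, newdata)
  denom <- sum((y - model$y_train_mean)^2)
  if (denom == 0) {
    abort_flav("degenerate test set: responses all equal the training mean",
               class = "flavperm_domain_error")
  }
  tibble(n = length(y), r2_pred = 1 - sum((y - yhat)^2) / denom,
         rmse = rmse(y, yhat))
}

#' Screen outlier compounds by training residual
#'
#' Single screening pass: fit on all candidate compounds, exclude every
#' compound whose residual (observed minus predicted response) exceeds
#' `residual_threshold`, and refit once on the remainder.  The rule is
#' deliberately not iterated, so a compound whose residual rises above the
#' threshold only after the refit is retained.  The rule is one-sided: it
#' targets compounds whose measured permeability is far *lower* than the
#' model predicts (pPapp is a negative log, so a large positive residual
#' means over-predicted absorption), the signature of assay instability
#' rather than model failure.
#'
#' @param data,response,descriptors,method,n_components,id_col As in
#'   [qspr_fit()].
#' @param residual_threshold Exclusion threshold on the signed residual,
#'   default 0.600 pPapp units.
#' @return A list: `excluded` (ids), `residuals` (tibble from the initial
#'   fit), `model` (the refit `qspr_model`).  Errors with class
#'   `flavperm_insufficient_data` if the exclusion leaves too few
#'   compounds to refit.
#' @export
screen_outliers <- function(data, response, descriptors,
                            residual_threshold = 0.600,
                            method = c("ols", "pls"), n_components = NULL,
                            id_col = "compound_id") {
  method <- match.arg(method)
  first <- qspr_fit(data, response, descriptors, method = method,
                    n_components = n_components, id_col = id_col,
                    compute_q2 = FALSE)
  out <- first$residuals$residual > residual_threshold
  excluded <- first$residuals$compound_id[out]
  keep <- data[!out, , drop = FALSE]
  if (nrow(keep) <= length(descriptors) + 2) {
    abort_flav(sprintf("outlier screen excluded %d compound(s), leaving too few (n = %d) to refit",
                       sum(out), nrow(keep)),
               class = "flavperm_insufficient_data")
  }
  refit <- qspr_fit(keep, response, descriptors, method = method,
                    n_components = n_components, id_col = id_col,
                    compute_q2 = FALSE)
  list(excluded = excluded, residuals = first$residuals, model = refit)
}
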