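# QSPR model fitting: OLS (via lm) and univariate NIPALS PLS with
# autoscaling.  Both return the same model object so downstream
# validation, prediction and reporting are method-agnostic.

# ---- fitting cores --------------------------------------------------------

fit_ols_core <- function(X, y) {
  Z <- cbind(`(Intercept)` = 1, X)
  dec <- qr(Z)
  if (dec$rank < ncol(Z)) {
    abort_flav("descriptor matrix is rank deficient; OLS fit is singular",
               class = "flavperm_singular_error")
  }
  beta <- qr.coef(dec, y)
  list(intercept = unname(beta[1]), coefficients = beta[-1])
}

# NIPALS PLS1 on autoscaled X and y; coefficients back-transformed to the
# original units so predictions are intercept + X %*% coefficients.
fit_pls_core <- function(X, y, n_components) {
  k <- ncol(X)
  xm <- colMeans(X); xs <- apply(X, 2, sd)
  ym <- mean(y); ys <- sd(y)
  if (any(xs == 0)) {
    abort_flav(sprintf("descriptor `%s` is constant; cannot autoscale",
                       colnames(X)[xs == 0][1]),
               class = "flavperm_domain_error")
  }
  if (ys == 0) {
    abort_flav("response is constant; cannot autoscale",
               class = "flavperm_domain_error")
  }
  Xs <- scale(X, center = xm, scale = xs)
  f <- (y - ym) / ys
  rank_x <- qr(Xs)$rank
  if (n_components > rank_x) {
    abort_flav(sprintf("n_components (%d) exceeds the rank of the descriptor matrix (%d)",
                       n_components, rank_x),
               class = "flavperm_singular_error")
  }
  W <- P <- matrix(0, k, n_components)
  q <- numeric(n_components)
  E <- Xs
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_h <- drop(E %*% w)
    tt <- sum(t_h^2)
    p <- drop(crossprod(E, t_h)) / tt
    q[h] <- sum(f * t_h) / tt
    E <- E - tcrossprod(t_h, p)
    f <- f - q[h] * t_h
    W[, h] <- w
    P[, h] <- p
  }
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  coefficients <- setNames(ys * b_scaled / xs, colnames(X))
  intercept <- ym - sum(coefficients * xm)
  list(intercept = intercept, coefficients = coefficients)
}

fit_core <- function(X, y, method, n_components = NULL) {
  if (method == "ols") fit_ols_core(X, y)
  else fit_pls_core(X, y, n_components)
}

# ---- user-facing fit ------------------------------------------------------

#' Fit a descriptor-based permeability model
#'
#' Fits `response ~ descriptors` on one row per compound, by ordinary least
#' squares or by univariate NIPALS partial least squares.  PLS works on
#' autoscaled (mean-centred, unit-variance) descriptors and response; its
#' coefficients are reported back-transformed to the original units, so for
#' both methods a prediction is `intercept + sum(coefficient * descriptor)`.
#' With all components retained on a full-rank descriptor matrix, PLS
#' reproduces the OLS solution; truncating components regularizes the fit.
#'
#' Fit statistics follow the usual definitions with `k` model degrees of
#' freedom (`k` = number of descriptors for OLS, number of PLS components
#' for PLS): `r2_adj = 1 - (1 - r2)(n - 1)/(n - k - 1)`,
#' `f_stat = (r2/k) / ((1 - r2)/(n - k - 1))`, `see = sqrt(RSS/(n - k - 1))`,
#' `rmse = sqrt(RSS/n)`.  A leave-one-out `q2` (see [loo_q2()]) is computed
#' unless `compute_q2 = FALSE`.
#'
#' @param data Data frame with the response, the descriptors and optionally
#'   an id column.
#' @param response Response column name (e.g. `"ppapp_exp"`).
#' @param descriptors Character vector of descriptor column names.
#' @param method `"ols"` or `"pls"`.
#' @param n_components Number of PLS components; `NULL` (default) picks the
#'   count in `1..k` that maximizes the leave-one-out Q2.
#' @param id_col Name of the compound id column, if present, used to label
#'   residuals and record training membership.
#' @param compute_q2 Compute the leave-one-out Q2 of the final model.
#' @return An object of class `qspr_model`; see [tidy.qspr_model()],
#'   [glance.qspr_model()], [augment.qspr_model()], [predict.qspr_model()].
#' @examples
#' study <- load_study("fang2017")
#' training <- dplyr::filter(study$descriptors, split == "training")
#' fit <- qspr_fit(training, "ppapp_exp",
#'                 c("QC3p", "E_sol", "SlogP_V3", "vsurf_ID1"))
#' glance(fit)
#' @export
qspr_fit <- function(data, response, descriptors,
                     method = c("ols", "pls"), n_components = NULL,
                     id_col = "compound_id", compute_q2 = TRUE) {
  method <- match.arg(method)
  check_columns(data, c(response, descriptors))
  if (length(descriptors) == 0) {
    abort_flav("need at least one descriptor", class = "flavperm_domain_error")
  }
  X <- as.matrix(data[descriptors])
  y <- data[[response]]
  if (anyNA(X) || anyNA(y)) {
    abort_flav("qspr_fit() requires complete cases",
               class = "flavperm_domain_error")
  }
  n <- nrow(X); k <- ncol(X)
  ids <- if (id_col %in% names(data)) data[[id_col]] else seq_len(n)

  if (method == "ols") {
    if (n <= k + 2) {
      abort_flav(sprintf("OLS needs n > k + 2 (n = %d, k = %d)", n, k),
                 class = "flavperm_insufficient_data")
    }
    n_components <- NULL
  } else {
    if (is.null(n_components)) {
      q2s <- vapply(seq_len(k), function(a) {
        loo_q2_core(X, y, method = "pls", n_components = a)$q2
      }, numeric(1))
      n_components <- which.max(q2s)
    }
    stopifnot(n_components >= 1, n_components <= k)
  }

  core <- fit_core(X, y, method, n_components)
  fitted <- drop(core$intercept + X %*% core$coefficients)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_model <- if (method == "ols") k else n_components
  r2 <- 1 - rss / tss
  coef_table <- NULL
  p_value <- NA_real_
  if (method == "ols") {
    lmfit <- lm(stats::reformulate(descriptors, response), data = data)
    # summary.lm warns on exact fits (r2 == 1); that case is legitimate here
    lmsum <- suppressWarnings(summary(lmfit))
    coef_table <- lmsum$coefficients
    fv <- lmsum$fstatistic
    p_value <- unname(stats::pf(fv[1], fv[2], fv[3], lower.tail = FALSE))
  } else {
    f_stat <- (r2 / df_model) / ((1 - r2) / (n - df_model - 1))
    p_value <- stats::pf(f_stat, df_model, n - df_model - 1, lower.tail = FALSE)
  }

  model <- structure(list(
    intercept = core$intercept,
    coefficients = core$coefficients,
    method = method,
    n_components = n_components,
    scaling = if (method == "pls") "autoscale" else "none",
    response = response,
    descriptors = descriptors,
    training_ids = ids,
    y_train_mean = mean(y),
    data = as_tibble(data[c(intersect(id_col, names(data)), response,
                            descriptors)]),
    id_col = if (id_col %in% names(data)) id_col else NULL,
    coef_table = coef_table,
    residuals = tibble(compound_id = ids, observed = y, fitted = fitted,
                       residual = res),
    stats = list(
      n = n, k = df_model, r2 = r2,
      r2_adj = 1 - (1 - r2) * (n - 1) / (n - df_model - 1),
      f_stat = (r2 / df_model) / ((1 - r2) / (n - df_model - 1)),
      p_value = p_value,
      see = sqrt(rss / (n - df_model - 1)),
      rmse = sqrt(rss / n),
      q2 = NA_real_, press = NA_real_
    )
  ), class = "qspr_model")

  if (compute_q2) {
    loo <- loo_q2_core(X, y, method, n_components)
    model$stats$q2 <- loo$q2
    model$stats$press <- loo$press
  }
  model
}

#' Predict permeability for new compounds
#'
#' @param object A `qspr_model`.
#' @param newdata Data frame containing every model descriptor; an error
#'   names any missing one.
#' @param scale `"ppapp"` (default) returns the modelled -log10 Papp;
#'   `"papp"` back-transforms to cm/s.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qspr_model <- function(object, newdata, scale = c("ppapp", "papp"),
                               ...) {
  scale <- match.arg(scale)
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing) > 0) {
    abort_flav(sprintf("newdata is missing model descriptor(s): %s",
                       paste0("`", missing, "`", collapse = ", ")),
               class = "flavperm_schema_error")
  }
  X <- as.matrix(newdata[object$descriptors])
  if (anyNA(X)) {
    abort_flav("newdata contains missing descriptor values",
               class = "flavperm_domain_error")
  }
  pp <- drop(object$intercept + X %*% object$coefficients)
  if (scale == "papp") ppapp_to_papp(pp) else pp
}

#' @export
print.qspr_model <- function(x, ...) {
  cat("<qspr_model> ", toupper(x$method),
      if (x$method == "pls") sprintf(" (%d components, autoscaled)", x$n_components),
      ", n = ", x$stats$n, "\n", sep = "")
  cat("  ", x$response, " = ", format(x$intercept, digits = 4), " + ",
      paste(sprintf("%s*%s", format(x$coefficients, digits = 3),
                    names(x$coefficients)), collapse = " + "), "\n", sep = "")
  cat(sprintf("  R2 = %.3f, R2_adj = %.3f, F = %.2f, SEE = %.3f, RMSE = %.3f",
              x$stats$r2, x$stats$r2_adj, x$stats$f_stat, x$stats$see,
              x$stats$rmse))
  if (!is.na(x$stats$q2)) cat(sprintf(", Q2(LOO) = %.3f", x$stats$q2))
  cat("\n")
  invisible(x)
}
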