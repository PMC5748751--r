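test_that("OLS recovers exact linear data and matches the normal equations", {
  d <- make_linear_data(n = 10)
  fit <- qspr_fit(d, "y", c("x1", "x2"))
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(3, -1), tolerance = 1e-10)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-12)

  # independent oracle: solve the normal equations directly on noisy data
  dn <- make_linear_data(n = 15, noise_sd = 0.5, seed = 9)
  fitn <- qspr_fit(dn, "y", c("x1", "x2"))
  Z <- cbind(1, as.matrix(dn[c("x1", "x2")]))
  beta <- solve(t(Z) %*% Z, t(Z) %*% dn$y)
  expect_equal(c(fitn$intercept, unname(fitn$coefficients)),
               unname(drop(beta)), tolerance = 1e-10)
  # residuals of an intercept model average zero
  expect_lt(abs(mean(fitn$residuals$residual)), 1e-10)
})

test_that("the training-set model reproduces the published fit statistics", {
  fit <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors)
  expect_equal(fit$stats$r2, 0.88128, tolerance = 1e-4)
  expect_equal(fit$stats$q2, 0.80856, tolerance = 1e-4)
  expect_equal(fit$stats$rmse, 0.141, tolerance = 0.005)
  # coefficients land on the published equation at its printed precision
  # (the published first coefficient, 1.358, sits 0.004 from the OLS value)
  expect_equal(fit$intercept, 4.715, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[c("E_sol", "SlogP_V3", "vsurf_ID1")]),
               c(0.059, 0.020, 0.056), tolerance = 0.01)
  expect_equal(unname(fit$coefficients["QC3p"]), 1.362, tolerance = 1e-3)
})

test_that("full-component PLS reproduces OLS and truncation follows the Krylov oracle", {
  for (seed in c(2, 5, 8)) {
    d <- make_linear_data(n = 18, beta = c(x1 = 1.5, x2 = -0.7, x3 = 0.2),
                          noise_sd = 0.4, seed = seed)
    desc <- c("x1", "x2", "x3")
    ols <- qspr_fit(d, "y", desc, compute_q2 = FALSE)
    pls_full <- qspr_fit(d, "y", desc, method = "pls", n_components = 3,
                         compute_q2 = FALSE)
    expect_equal(pls_full$coefficients, ols$coefficients, tolerance = 1e-9)
    expect_equal(pls_full$intercept, ols$intercept, tolerance = 1e-9)
    expect_lte(pls_full$stats$r2, ols$stats$r2 + 1e-8)

    # truncated PLS: coefficients are the least-squares solution restricted
    # to the Krylov subspace span{s, Ms, ...}, s = X'y, M = X'X (autoscaled)
    for (a in 1:2) {
      X <- scale(as.matrix(d[desc]))
      yv <- d$y; ys <- (yv - mean(yv)) / sd(yv)
      s <- drop(crossprod(X, ys)); M <- crossprod(X)
      K <- matrix(s, ncol = 1)
      if (a > 1) for (h in 2:a) K <- cbind(K, M %*% K[, h - 1, drop = FALSE])
      gamma <- qr.coef(qr(X %*% K), ys)
      b_oracle <- drop(K %*% gamma) * sd(yv) / attr(X, "scaled:scale")
      pls_a <- qspr_fit(d, "y", desc, method = "pls", n_components = a,
                        compute_q2 = FALSE)
      expect_equal(unname(pls_a$coefficients), unname(b_oracle),
                   tolerance = 1e-8)
      expect_lte(pls_a$stats$r2, ols$stats$r2 + 1e-8)
    }
  }
})

test_that("PLS on the study training set equals OLS at full rank", {
  ols <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors,
                  compute_q2 = FALSE)
  pls <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors,
                  method = "pls", n_components = 4, compute_q2 = FALSE)
  expect_equal(pls$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(pls$intercept, ols$intercept, tolerance = 1e-8)
})

test_that("automatic PLS component count maximizes the leave-one-out Q2", {
  auto <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors,
                   method = "pls")
  by_hand <- vapply(1:4, function(a) {
    loo_q2(fang_training, "ppapp_exp", canonical_descriptors,
           method = "pls", n_components = a)$q2
  }, numeric(1))
  expect_equal(auto$n_components, which.max(by_hand))
  expect_equal(auto$stats$q2, max(by_hand))
})

test_that("degenerate designs raise singularity errors", {
  d <- make_linear_data(n = 12)
  d$x3 <- d$x1 + d$x2 # rank-deficient
  expect_error(qspr_fit(d, "y", c("x1", "x2", "x3"), compute_q2 = FALSE),
               class = "flavperm_singular_error")
  expect_error(qspr_fit(d, "y", c("x1", "x2", "x3"), method = "pls",
                        n_components = 3, compute_q2 = FALSE),
               class = "flavperm_singular_error")
  expect_error(qspr_fit(d[1:4, ], "y", c("x1", "x2"), compute_q2 = FALSE),
               class = "flavperm_insufficient_data")
})

test_that("prediction is the linear form and names missing descriptors", {
  fit <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors,
                  compute_q2 = FALSE)
  zeros <- tibble::tibble(QC3p = 0, E_sol = 0, SlogP_V3 = 0, vsurf_ID1 = 0)
  expect_equal(predict(fit, zeros), fit$intercept)
  one <- fang_training[1, ]
  expect_equal(predict(fit, one),
               fit$intercept + sum(unlist(one[canonical_descriptors]) *
                                     fit$coefficients))
  expect_equal(predict(fit, one, scale = "papp"),
               ppapp_to_papp(predict(fit, one)))
  # published equation at the compound-1 descriptors gives 4.723
  pub <- fit
  pub$intercept <- 4.715
  pub$coefficients[] <- c(1.358, 0.059, 0.020, 0.056)[
    match(names(pub$coefficients), canonical_descriptors)]
  expect_equal(predict(pub, zeros), 4.715)
  c1 <- tibble::tibble(QC3p = 0.010, E_sol = -0.789, SlogP_V3 = 0,
                       vsurf_ID1 = 0.736)
  expect_equal(predict(pub, c1), 4.723, tolerance = 5e-4)
  # all coefficients positive: raising any descriptor raises pPapp
  for (dcol in canonical_descriptors) {
    up <- c1; up[[dcol]] <- up[[dcol]] + 1
    expect_gt(predict(pub, up), predict(pub, c1))
  }
  expect_error(predict(fit, c1[, -2]), "E_sol",
               class = "flavperm_schema_error")
})

test_that("tidy, glance and augment expose the model in broom form", {
  fit <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", canonical_descriptors))
  expect_true(all(td$p.value < 0.01)) # every selected term is significant
  gl <- glance(fit)
  expect_equal(gl$nobs, 22)
  expect_equal(gl$r.squared, fit$stats$r2)
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$ppapp_exp - aug$.fitted)
  expect_equal(nrow(aug), 22)
})

test_that("model JSON round trip predicts identically", {
  fit <- qspr_fit(fang_training, "ppapp_exp", canonical_descriptors)
  path <- withr::local_tempfile(fileext = ".json")
  qspr_model_to_json(fit, path)
  back <- qspr_model_from_json(path)
  expect_equal(predict(back, fang_test), predict(fit, fang_test))
  expect_equal(back$stats$r2, fit$stats$r2)
  expect_equal(back$training_ids, fit$training_ids)
})
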