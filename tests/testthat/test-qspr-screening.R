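test_that("correlation matrix reproduces the training-block Pearson table", {
  cm <- correlation_matrix(fang_training, "ppapp_exp")
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  printed <- c(SlogP_V3 = 0.738, QC3p = 0.576, E_sol = 0.045,
               vsurf_ID1 = 0.407)
  for (d in names(printed)) {
    expect_lt(abs(cm["ppapp_exp", d] - printed[[d]]), 5e-4)
  }
  inter <- rbind(c("QC3p", "E_sol", -0.273), c("QC3p", "SlogP_V3", 0.223),
                 c("QC3p", "vsurf_ID1", 0.214), c("E_sol", "SlogP_V3", -0.103),
                 c("E_sol", "vsurf_ID1", -0.363))
  for (i in seq_len(nrow(inter))) {
    expect_lt(abs(cm[inter[i, 1], inter[i, 2]] - as.numeric(inter[i, 3])),
              5e-4)
  }
  # the reported SlogP_V3/vsurf_ID1 entry (-0.148) matches in magnitude;
  # the recomputed coefficient is positive
  expect_lt(abs(cm["SlogP_V3", "vsurf_ID1"] - 0.148), 5e-4)
  # largest inter-descriptor magnitude stays well under the 0.7 filter
  desc <- canonical_descriptors
  block <- abs(cm[desc, desc]); diag(block) <- 0
  expect_lt(max(block), 0.7)
})

test_that("correlation matrix is invariant to affine rescaling of a column", {
  cm <- correlation_matrix(fang_training, "ppapp_exp")
  shifted <- fang_training
  shifted$E_sol <- 100 + 7 * shifted$E_sol
  shifted$SlogP_V3 <- 0.01 * shifted$SlogP_V3 - 3
  cm2 <- correlation_matrix(shifted, "ppapp_exp")
  expect_equal(unclass(cm2), unclass(cm))
})

test_that("correlation matrix guards its preconditions", {
  expect_error(correlation_matrix(fang_training[1:2, ], "ppapp_exp"),
               class = "flavperm_insufficient_data")
  const <- fang_training
  const$E_sol <- 5
  expect_error(correlation_matrix(const, "ppapp_exp"), "E_sol",
               class = "flavperm_domain_error")
  # exact collinearity gives off-diagonal +/-1
  dup <- make_linear_data(n = 4)
  dup$x2 <- -2 * dup$x1 + 1
  cmd <- correlation_matrix(dup, "y", c("x1", "x2"))
  expect_equal(cmd["x1", "x2"], -1)
})

test_that("collinearity filter keeps the whole independent descriptor set", {
  cm <- correlation_matrix(fang_training, "ppapp_exp")
  res <- filter_collinear(cm, threshold = 0.7)
  expect_setequal(res$retained, canonical_descriptors)
  expect_equal(nrow(res$dropped), 0)
})

test_that("collinearity filter drops weaker duplicates until no violation", {
  # two identical descriptors: exactly one dropped (the alphabetically
  # later one on a response tie)
  d <- make_linear_data(n = 12)
  d$x1b <- d$x1
  res <- filter_collinear(correlation_matrix(d, "y", c("x1", "x1b", "x2")))
  expect_setequal(res$retained, c("x1", "x2"))
  expect_equal(res$dropped$dropped, "x1b")

  # three mutually collinear descriptors (|r| = 0.9): only one survives,
  # the one most correlated with the response
  m <- matrix(c(
    1.0, 0.5, 0.4, 0.3,
    0.5, 1.0, 0.9, 0.9,
    0.4, 0.9, 1.0, 0.9,
    0.3, 0.9, 0.9, 1.0
  ), 4, 4, dimnames = list(c("y", "d1", "d2", "d3"),
                           c("y", "d1", "d2", "d3")))
  res3 <- filter_collinear(make_cormat(m, "y"), threshold = 0.7)
  expect_equal(res3$retained, "d1")
  expect_equal(nrow(res3$dropped), 2)
  # stopping condition: no retained pair exceeds the threshold
  expect_true(all(abs(m[res3$retained, res3$retained]) <= 0.7 |
                    diag(length(res3$retained)) == 1))
})

test_that("stepwise selection finds the four descriptors on the study data", {
  sel <- stepwise_select(fang_training, "ppapp_exp")
  expect_setequal(as.character(sel), canonical_descriptors)
  trace <- attr(sel, "trace")
  expect_true(all(trace$p_value[trace$action == "enter"] < 0.05))
})

test_that("stepwise selection recovers a noiseless single signal among decoys", {
  withr::with_seed(11, {
    X <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(NULL, paste0("d", 1:6)))
  })
  d <- tibble::as_tibble(X)
  d$y <- 1 + 2 * d$d3 # exact signal in d3, five pure-noise decoys
  sel <- stepwise_select(d, "y", paste0("d", 1:6))
  expect_equal(as.character(sel), "d3")
})

test_that("stepwise selection under the null stays empty at the nominal rate", {
  sizes <- vapply(1:100, function(s) {
    d <- fang_training[canonical_descriptors]
    withr::with_seed(s, d$y <- rnorm(nrow(d)))
    sel <- tryCatch(stepwise_select(d, "y", canonical_descriptors),
                    flavperm_empty_selection = function(e) character())
    length(sel)
  }, numeric(1))
  expect_equal(median(sizes), 0)
  # any-entry rate is a family-wise rate over 4 candidates at enter_p 0.05:
  # bounded well away from certainty, above zero
  expect_lt(mean(sizes > 0), 0.4)
  # a candidate orthogonal to a trend never passes entry
  null_d <- tibble::tibble(x = rep(c(-1, 1), 11), y = seq_len(22))
  expect_error(stepwise_select(null_d, "y", "x"),
               class = "flavperm_empty_selection")
})
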