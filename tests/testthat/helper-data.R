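# shared fixtures built in code

# packaged study, loaded once per test run
fang <- load_study("fang2017")
fang_training <- dplyr::filter(fang$descriptors, split == "training")
fang_test <- dplyr::filter(fang$descriptors, split == "test")
canonical_descriptors <- c("QC3p", "E_sol", "SlogP_V3", "vsurf_ID1")

# small exact linear dataset: y = intercept + X beta (no noise)
make_linear_data <- function(n = 10, beta = c(x1 = 3, x2 = -1),
                             intercept = 2, noise_sd = 0, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n, length(beta),
                dimnames = list(NULL, names(beta)))
    y <- intercept + drop(X %*% beta) + rnorm(n, 0, noise_sd)
  })
  tibble::tibble(compound_id = seq_len(n), !!!as.data.frame(X), y = y)
}

# correlation-matrix object built directly (for filter_collinear edge cases)
make_cormat <- function(m, response) {
  structure(m, class = c("flav_cormat", class(m)), response = response)
}
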