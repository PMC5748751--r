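# Seeded synthetic-data generators with the statistical structure the
# analysis assumes: a linear descriptor -> pPapp response with Gaussian
# noise and configurable descriptor inter-correlation, and a noisy
# bidirectional transwell assay under sink conditions.

# Defaults anchored to the packaged study: descriptor marginals are the
# empirical means/SDs of the 28 modelled compounds, the inter-descriptor
# correlation target is the reported Pearson block, and the true model is
# the published four-descriptor equation.
default_descriptor_means <- c(QC3p = 0.0754, E_sol = -1.156,
                              SlogP_V3 = 9.924, vsurf_ID1 = 2.119)
default_descriptor_sds <- c(QC3p = 0.1426, E_sol = 3.384,
                            SlogP_V3 = 13.070, vsurf_ID1 = 2.507)
default_descriptor_cor <- matrix(c(
  1.000, -0.273, 0.223, 0.214,
  -0.273, 1.000, -0.103, -0.363,
  0.223, -0.103, 1.000, -0.148,
  0.214, -0.363, -0.148, 1.000
), 4, 4, dimnames = list(names(default_descriptor_means),
                         names(default_descriptor_means)))
default_true_coefficients <- c(QC3p = 1.358, E_sol = 0.059,
                               SlogP_V3 = 0.020, vsurf_ID1 = 0.056)

#' Simulate a descriptor/permeability dataset
#'
#' Draws descriptor vectors from a multivariate normal with configurable
#' marginals and inter-descriptor correlation, generates the response as
#' `intercept + sum(beta * x) + N(0, noise_sd)`, and assigns a
#' training/test split.  The defaults emulate the packaged 28-compound
#' study: descriptor means/SDs match its descriptor table, the correlation
#' target is its reported Pearson block, the true model is its published
#' four-descriptor equation, `noise_sd` is its reported training RMSE
#' (0.141 pPapp units), and the split is 22 training / 6 test.
#'
#' The generator is a pure function of its arguments: the same `seed`
#' yields a bit-identical table.
#'
#' @param n_compounds Number of compounds, >= 4.
#' @param descriptor_means,descriptor_sds Named numeric vectors of
#'   descriptor marginals.
#' @param descriptor_cor Target inter-descriptor Pearson matrix; must be
#'   symmetric positive definite.
#' @param true_intercept,true_coefficients True generating model.
#' @param noise_sd Response noise standard deviation, >= 0.
#' @param n_test Number of compounds assigned to the test split (at
#'   random); scaled proportionally if `n_compounds` differs from 28.
#' @param seed Integer seed; every draw is governed by it.
#' @return A tibble: `compound_id`, one column per descriptor,
#'   `ppapp_exp`, `split`.
#' @examples
#' sim <- sim_qspr_study(n_compounds = 28, seed = 1)
#' head(sim)
#' @export
sim_qspr_study <- function(n_compounds = 28,
                           descriptor_means = default_descriptor_means,
                           descriptor_sds = default_descriptor_sds,
                           descriptor_cor = default_descriptor_cor,
                           true_intercept = 4.715,
                           true_coefficients = default_true_coefficients,
                           noise_sd = 0.141,
                           n_test = max(0L, round(n_compounds * 6 / 28)),
                           seed = 20171129) {
  stopifnot(n_compounds >= 4, noise_sd >= 0, n_test < n_compounds)
  k <- length(descriptor_means)
  stopifnot(length(descriptor_sds) == k,
            identical(dim(descriptor_cor), c(k, k)),
            length(true_coefficients) == k)
  if (max(abs(descriptor_cor - t(descriptor_cor))) > 1e-10) {
    abort_flav("descriptor_cor must be symmetric",
               class = "flavperm_domain_error")
  }
  ev <- eigen(descriptor_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort_flav("descriptor_cor must be positive definite",
               class = "flavperm_domain_error")
  }
  check_positive(descriptor_sds, "descriptor_sds")
  sigma <- diag(descriptor_sds) %*% descriptor_cor %*% diag(descriptor_sds)
  withr::with_seed(seed, {
    X <- MASS::mvrnorm(n_compounds, mu = descriptor_means, Sigma = sigma)
    y <- true_intercept + drop(X %*% true_coefficients) +
      rnorm(n_compounds, 0, noise_sd)
    test_ids <- sample.int(n_compounds, n_test)
  })
  colnames(X) <- names(descriptor_means)
  split <- rep("training", n_compounds)
  split[test_ids] <- "test"
  tibble(compound_id = seq_len(n_compounds), !!!as.data.frame(X),
         ppapp_exp = y,
         split = factor(split, levels = c("training", "test", "excluded")))
}

#' Simulate a bidirectional transwell transport experiment
#'
#' Generates replicate receiver-appearance rates for both transport
#' directions of one compound under sink-condition linear flux: the true
#' rate is `papp * area * c0` (with the secretory Papp equal to
#' `papp_true_ab * ratio_p_true`), perturbed by multiplicative Gaussian
#' noise with coefficient of variation `cv`.  The defaults mirror a
#' 12-well hanging-insert assay: 1.12 cm^2 membrane, 40 uM dosing
#' (0.04 umol/cm^3), 60 min incubation, apical volume 0.4 mL and
#' basolateral volume 1.95 mL.
#'
#' The linear-flux model only holds while the receiver stays below 10% of
#' the dose (sink condition); parameter combinations that violate it raise
#' an error advising a shorter duration.
#'
#' @param papp_true_ab True absorptive Papp, cm/s.
#' @param ratio_p_true True efflux ratio; the secretory Papp is
#'   `papp_true_ab * ratio_p_true`.
#' @param area Insert area, cm^2.
#' @param c0 Donor concentration, umol/cm^3.
#' @param duration Incubation time, minutes.
#' @param cv Coefficient of variation of the multiplicative rate noise.
#' @param n_replicates Replicates per direction.
#' @param donor_volume Named vector, donor volume in cm^3 per direction.
#' @param seed Integer seed.
#' @return A tibble of `2 * n_replicates` assay rows: `direction`,
#'   `replicate`, `rate` (umol/s), `area`, `c0`, `duration`.
#' @examples
#' assay <- sim_transport_assay(5e-6, ratio_p_true = 4, seed = 1)
#' dplyr::summarise(dplyr::group_by(assay, direction),
#'                  papp = mean(compute_papp(rate, area, c0)))
#' @export
sim_transport_assay <- function(papp_true_ab, ratio_p_true = 1,
                                area = 1.12, c0 = 0.04, duration = 60,
                                cv = 0.05, n_replicates = 3,
                                donor_volume = c(AtoB = 0.4, BtoA = 1.95),
                                seed = 20171129) {
  check_positive(c(papp_true_ab, ratio_p_true, area, c0, duration),
                 "assay parameters")
  check_positive(cv, "cv", strict = FALSE)
  stopifnot(n_replicates >= 1, all(c("AtoB", "BtoA") %in% names(donor_volume)))
  papp <- c(AtoB = papp_true_ab, BtoA = papp_true_ab * ratio_p_true)
  t_sec <- duration * 60
  # receiver amount after `duration` as a fraction of the dosed amount
  frac <- papp * area * t_sec / donor_volume[names(papp)]
  if (any(frac >= 0.10)) {
    worst <- names(papp)[which.max(frac)]
    abort_flav(
      sprintf("sink condition violated (%s receiver would reach %.0f%% of the dose); use a shorter duration",
              worst, 100 * max(frac)),
      class = "flavperm_domain_error"
    )
  }
  true_rate <- papp * area * c0
  withr::with_seed(seed, {
    noise <- rnorm(2 * n_replicates, mean = 1, sd = cv)
  })
  tibble(
    direction = rep(c("AtoB", "BtoA"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    rate = rep(unname(true_rate), each = n_replicates) * noise,
    area = area, c0 = c0, duration = duration
  )
}
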