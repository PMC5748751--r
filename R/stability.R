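# Solvent stability, mass-balance recovery and monolayer QC gates.

#' Relative concentration of a compound in assay buffer
#'
#' Ratio of the chromatographic peak area of a compound dissolved in
#' D-Hank's buffer to the peak area of the same compound in methanol (the
#' reference solvent), expressed in percent.  Values above 100% are legal:
#' they only mean the buffer peak exceeded the methanol peak.
#'
#' @param peak_dhanks Peak area in D-Hank's buffer.
#' @param peak_methanol Peak area in methanol. Must be > 0.
#' @return Percent, vectorized.
#' @examples
#' relative_concentration(34.12, 100) # 34.12% -> unstable in buffer
#' @export
relative_concentration <- function(peak_dhanks, peak_methanol) {
  check_positive(peak_methanol, "peak_methanol")
  100 * peak_dhanks / peak_methanol
}

#' Classify solvent stability from the relative concentration
#'
#' At or above 50% the compound is considered stable in buffer; below 40%
#' unstable.  The 40-50% band, for which the study states no rule, is
#' classified `questionable`.
#'
#' @param rel_conc Relative concentration in percent, >= 0.
#' @return Factor with levels stable, questionable, unstable.
#' @examples
#' classify_stability(c(87.51, 45, 34.12))
#' @export
classify_stability <- function(rel_conc) {
  check_positive(rel_conc, "rel_conc", strict = FALSE)
  out <- rep("questionable", length(rel_conc))
  out[rel_conc >= 50] <- "stable"
  out[rel_conc < 40] <- "unstable"
  out[is.na(rel_conc)] <- NA
  factor(out, levels = c("stable", "questionable", "unstable"))
}

#' Mass-balance recovery of a transport assay
#'
#' Total compound found in the receiver chamber, the donor chamber and the
#' cell monolayer, as a percentage of the dosed amount.  Low recovery
#' indicates degradation, metabolism or non-specific binding during the
#' assay.
#'
#' @param receiver_amount,donor_amount,cellular_amount Amounts recovered in
#'   each compartment, umol. Must be >= 0.
#' @param dosed_amount Amount dosed into the donor chamber, umol. Must be > 0.
#' @return Percent recovery, vectorized.
#' @examples
#' mass_balance_recovery(0.2, 0.5, 0.1, 1.0) # 80%
#' @export
mass_balance_recovery <- function(receiver_amount, donor_amount,
                                  cellular_amount, dosed_amount) {
  check_positive(receiver_amount, "receiver_amount", strict = FALSE)
  check_positive(donor_amount, "donor_amount", strict = FALSE)
  check_positive(cellular_amount, "cellular_amount", strict = FALSE)
  check_positive(dosed_amount, "dosed_amount")
  100 * (receiver_amount + donor_amount + cellular_amount) / dosed_amount
}

#' Relative standard deviation
#'
#' @param mean Mean value, must be > 0.
#' @param sd Standard deviation, must be >= 0.
#' @return RSD in percent: `100 * sd / mean`.
#' @examples
#' rsd(96.95, 1.67) # 1.72%
#' @export
rsd <- function(mean, sd) {
  check_positive(mean, "mean")
  check_positive(sd, "sd", strict = FALSE)
  100 * sd / mean
}

#' Monolayer integrity quality-control gate
#'
#' A Caco-2 monolayer qualifies for transport assays only if its
#' trans-epithelial electrical resistance is above `teer_min` and the
#' paracellular Lucifer yellow flux is below `ly_max`.  Both boundaries are
#' exclusive.
#'
#' @param teer TEER in Ohm cm^2, >= 0.
#' @param ly_papp Lucifer yellow Papp in cm/s, >= 0.
#' @param teer_min TEER gate, default 600 Ohm cm^2.
#' @param ly_max Flux gate, default 0.5e-6 cm/s.
#' @return A one-row tibble per monolayer: `teer`, `ly_papp`, `pass`, and
#'   `reasons` (comma-separated violated gates, `""` when passing).
#' @examples
#' qc_monolayer(700, 3.58e-7)
#' qc_monolayer(c(600, 1000), c(1e-7, 5e-7))
#' @export
qc_monolayer <- function(teer, ly_papp, teer_min = 600, ly_max = 0.5e-6) {
  check_positive(teer, "teer", strict = FALSE)
  check_positive(ly_papp, "ly_papp", strict = FALSE)
  teer_ok <- teer > teer_min
  flux_ok <- ly_papp < ly_max
  reasons <- mapply(function(t_ok, f_ok) {
    paste(c(if (!t_ok) "TEER not above threshold",
            if (!f_ok) "Lucifer yellow flux not below threshold"),
          collapse = "; ")
  }, teer_ok, flux_ok)
  tibble(teer = teer, ly_papp = ly_papp, pass = teer_ok & flux_ok,
         reasons = unname(reasons))
}

#' Stability and recovery summary for a study
#'
#' Joins the solvent-stability classification with the mass-balance
#' recovery gate.  A compound with no relative-concentration measurement is
#' classified `unknown`.
#'
#' @param study A `flav_study`.
#' @param recovery_gate Acceptance threshold (percent) that both recovery
#'   directions must exceed, default 60.
#' @return A tibble: `compound_id`, `rel_conc`, `stability_class`, recovery
#'   columns with their RSDs, and `recovery_ok` (`NA` where recovery was not
#'   measured).
#' @examples
#' stability_summary(load_study("fang2017"))
#' @export
stability_summary <- function(study, recovery_gate = 60) {
  stopifnot(inherits(study, "flav_study"))
  st <- study$stability
  cls <- as.character(classify_stability(st$rel_conc))
  cls[is.na(cls)] <- "unknown"
  st %>%
    mutate(
      stability_class = factor(cls, levels = c("stable", "questionable",
                                               "unstable", "unknown")),
      recovery_ok = .data$recovery_ab > recovery_gate &
        .data$recovery_ba > recovery_gate
    ) %>%
    select("compound_id", "rel_conc", "rel_conc_code", "stability_class",
           "recovery_ab", "recovery_ab_sd", "rsd_ab",
           "recovery_ba", "recovery_ba_sd", "rsd_ba", "recovery_ok")
}
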