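# Bidirectional transwell transport analytics: Papp, efflux ratio,
# mechanism classification, cellular accumulation, Papp-CA correlation.

#' Apparent permeability coefficient from a transwell assay
#'
#' `Papp = (dQ/dt) / (A * C0)`: the appearance rate of compound in the
#' receiver chamber normalized by insert area and initial donor
#' concentration.  With `rate` in umol/s, `area` in cm^2 and `c0` in
#' umol/cm^3 (1 umol/cm^3 = 1 mM), the result is in cm/s.
#'
#' @param rate Appearance rate in the receiver chamber, umol/s.
#' @param area Insert membrane area, cm^2. Must be > 0.
#' @param c0 Initial donor concentration, umol/cm^3. Must be > 0.
#' @return Papp in cm/s.
#' @examples
#' compute_papp(4e-8, area = 1, c0 = 0.04) # 1e-6 cm/s
#' @export
compute_papp <- function(rate, area, c0) {
  check_positive(area, "area")
  check_positive(c0, "c0")
  rate / (area * c0)
}

#' Efflux ratio of bidirectional permeability
#'
#' `ratio_p = Papp(B to A) / Papp(A to B)`: secretory over absorptive
#' permeability.  A ratio near 1 is consistent with passive diffusion; a
#' high ratio implicates apically directed efflux transport.
#'
#' @param papp_ab Absorptive (apical-to-basolateral) Papp, cm/s. Must be > 0.
#' @param papp_ba Secretory (basolateral-to-apical) Papp, cm/s.
#' @return Dimensionless ratio, vectorized.
#' @examples
#' efflux_ratio(6.32e-6, 26.08e-6) # 4.13, strong efflux signature
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  check_positive(papp_ab, "papp_ab")
  papp_ba / papp_ab
}

#' Transport mechanism classification bands
#'
#' Cut-offs on the efflux ratio: `passive` is the closed interval
#' `passive[1]`-`passive[2]`; ratios strictly above `efflux` implicate
#' active efflux; ratios at or below `absorptive` indicate preferential
#' absorptive transport.  The gaps between bands are classified
#' `indeterminate` (e.g. quercetin at 1.84, which sits between the passive
#' and efflux bands and is left unresolved).  The absorptive bound is
#' inclusive so that a ratio printed as 0.50 falls in the absorptive class.
#'
#' @param passive Length-2 numeric, closed passive-diffusion band.
#' @param efflux Scalar; ratios strictly above it are efflux-implicated.
#' @param absorptive Scalar; ratios at or below it are preferential
#'   absorptive.
#' @return A named list of band edges for [classify_transport()].
#' @export
transport_bands <- function(passive = c(0.8, 1.5), efflux = 2.0,
                            absorptive = 0.5) {
  stopifnot(length(passive) == 2, passive[1] < passive[2],
            absorptive > 0, absorptive < passive[1], efflux > passive[2])
  list(passive = passive, efflux = efflux, absorptive = absorptive)
}

transport_mechanisms <- c("passive", "efflux_implicated",
                          "preferential_absorptive", "indeterminate")

#' Classify the transport mechanism from an efflux ratio
#'
#' @param ratio_p Efflux ratio(s), must be > 0.
#' @param bands Band edges from [transport_bands()].
#' @return A factor with levels passive, efflux_implicated,
#'   preferential_absorptive, indeterminate.
#' @examples
#' classify_transport(c(1.10, 4.13, 0.37, 1.84))
#' @export
classify_transport <- function(ratio_p, bands = transport_bands()) {
  check_positive(ratio_p, "ratio_p")
  out <- rep("indeterminate", length(ratio_p))
  out[ratio_p <= bands$absorptive] <- "preferential_absorptive"
  out[ratio_p >= bands$passive[1] & ratio_p <= bands$passive[2]] <- "passive"
  out[ratio_p > bands$efflux] <- "efflux_implicated"
  out[is.na(ratio_p)] <- NA
  factor(out, levels = transport_mechanisms)
}

#' Cellular accumulation ratio
#'
#' `ratio_c = CA(B to A) / CA(A to B)`: how much more compound is retained
#' in the monolayer after secretory than after absorptive transport.
#' Missing accumulation (ND/NT) propagates to a missing ratio.
#'
#' @param ca_ab,ca_ba Cellular accumulation per direction, umol/g protein.
#' @return Dimensionless ratio; `NA` where either input is missing.
#' @examples
#' accumulation_ratio(1.182, 3.272) # 2.77
#' @export
accumulation_ratio <- function(ca_ab, ca_ba) {
  if (any(ca_ab <= 0, na.rm = TRUE)) {
    abort_flav("`ca_ab` must be > 0 where measured.",
               class = "flavperm_domain_error")
  }
  ca_ba / ca_ab
}

#' Normalize a cellular amount by protein content
#'
#' @param amount Amount of compound in the cell lysate, umol.
#' @param protein Cellular protein, g. Must be > 0.
#' @return Accumulation in umol/g protein.
#' @export
normalize_ca <- function(amount, protein) {
  check_positive(protein, "protein")
  amount / protein
}

#' Summarize bidirectional transport and accumulation for a study
#'
#' Recomputes the efflux ratio from the per-compound mean Papp values,
#' classifies the transport mechanism, and joins the accumulation ratio and
#' the direction-difference flag.  This is the per-compound transport report
#' of the analysis.
#'
#' @param study A `flav_study` from [load_study()].
#' @param bands Classification bands, see [transport_bands()].
#' @param use_printed_ratio If `TRUE`, classify on the ratio column carried
#'   in the transport table (the value as printed in the source study)
#'   instead of the recomputed one.  Default `FALSE`.
#' @return A tibble with one row per compound: `compound_id`, `name`,
#'   `subclass`, `is_glycoside`, Papp means (cm/s), `ratio_p`, `mechanism`,
#'   accumulation columns, `ratio_c` and `direction_diff`.
#' @examples
#' transport_summary(load_study("fang2017"))
#' @export
transport_summary <- function(study, bands = transport_bands(),
                              use_printed_ratio = FALSE) {
  stopifnot(inherits(study, "flav_study"))
  tr <- study$transport %>%
    mutate(
      ratio_p_printed = .data$ratio_p,
      ratio_p = efflux_ratio(.data$papp_ab, .data$papp_ba)
    )
  ratio_for_class <- if (use_printed_ratio) tr$ratio_p_printed else tr$ratio_p
  tr$mechanism <- classify_transport(ratio_for_class, bands)
  study$compounds %>%
    select("compound_id", "name", "subclass", "is_glycoside") %>%
    left_join(tr, by = "compound_id") %>%
    left_join(
      study$accumulation %>%
        mutate(ratio_c = accumulation_ratio(.data$ca_ab, .data$ca_ba)) %>%
        select("compound_id", "ca_ab", "ca_ba", "ratio_c", "direction_diff"),
      by = "compound_id"
    )
}

#' Correlation between permeability and cellular accumulation
#'
#' Pearson correlation between per-compound Papp and cellular accumulation
#' in one transport direction, over the compounds with a measured
#' accumulation value (ND/NT excluded).  A low `r_squared` indicates that
#' how much compound the monolayer retains says little about how fast the
#' compound crosses it.
#'
#' @param study A `flav_study`.
#' @param direction `"AtoB"` or `"BtoA"`.
#' @return A one-row tibble: `direction`, `n`, `r`, `r_squared`.
#' @examples
#' correlate_papp_ca(load_study("fang2017"), "AtoB")
#' @export
correlate_papp_ca <- function(study, direction = c("AtoB", "BtoA")) {
  stopifnot(inherits(study, "flav_study"))
  direction <- match.arg(direction)
  joined <- left_join(study$transport, study$accumulation, by = "compound_id")
  papp <- if (direction == "AtoB") joined$papp_ab else joined$papp_ba
  ca <- if (direction == "AtoB") joined$ca_ab else joined$ca_ba
  ok <- !is.na(papp) & !is.na(ca)
  if (sum(ok) < 3) {
    abort_flav("need at least 3 compounds with both Papp and accumulation measured",
               class = "flavperm_insufficient_data")
  }
  r <- cor(papp[ok], ca[ok])
  tibble(direction = direction, n = sum(ok), r = r, r_squared = r^2)
}

#' Compare cellular accumulation between transport directions
#'
#' Two-sided two-sample Student's t-test with pooled variance on replicate
#' accumulation measurements from the two directions, flagged at the 0.05
#' and 0.01 levels.
#'
#' @param reps_ab,reps_ba Numeric replicate vectors (umol/g) for the
#'   absorptive and secretory direction.
#' @param alpha_levels Two significance thresholds, default `c(0.05, 0.01)`.
#' @return A one-row tibble: `n_ab`, `n_ba`, `statistic`, `p_value`, and
#'   `direction_diff`, a factor in ns / p<0.05 / p<0.01 / unevaluable.
#' @examples
#' compare_ca_directions(c(1.1, 1.2, 1.0), c(3.0, 3.3, 3.1))
#' @export
compare_ca_directions <- function(reps_ab, reps_ba,
                                  alpha_levels = c(0.05, 0.01)) {
  reps_ab <- reps_ab[!is.na(reps_ab)]
  reps_ba <- reps_ba[!is.na(reps_ba)]
  alpha_levels <- sort(alpha_levels, decreasing = TRUE)
  if (length(reps_ab) < 2 || length(reps_ba) < 2) {
    return(tibble(n_ab = length(reps_ab), n_ba = length(reps_ba),
                  statistic = NA_real_, p_value = NA_real_,
                  direction_diff = factor("unevaluable", direction_levels)))
  }
  if (var(reps_ab) == 0 && var(reps_ba) == 0 &&
      mean(reps_ab) == mean(reps_ba)) {
    # degenerate: identical constant samples, no evidence of a difference
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(reps_ab, reps_ba, var.equal = TRUE)
  }
  flag <- if (tt$p.value < alpha_levels[2]) "p<0.01"
          else if (tt$p.value < alpha_levels[1]) "p<0.05"
          else "ns"
  tibble(n_ab = length(reps_ab), n_ba = length(reps_ba),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         direction_diff = factor(flag, direction_levels))
}
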