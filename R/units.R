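#' Convert between Papp and its negative log scale
#'
#' Apparent permeability coefficients (Papp, cm/s) span several orders of
#' magnitude across a compound series, so permeability models work on
#' `pPapp = -log10(Papp)`, the same transform used for pKa or pIC50.
#' `papp_to_ppapp()` maps cm/s onto that scale and `ppapp_to_papp()` inverts
#' it; the round trip is exact to floating-point precision.
#'
#' @param papp Apparent permeability in cm/s. Must be strictly positive.
#' @param ppapp Negative decadic logarithm of Papp (dimensionless).
#'
#' @return A numeric vector of the same length as the input.
#'
#' @examples
#' papp_to_ppapp(22.35e-6) # 4.651
#' ppapp_to_papp(5)        # 1e-5 cm/s
#' @export
papp_to_ppapp <- function(papp) {
  if (any(!is.finite(papp) | papp <= 0, na.rm = FALSE)) {
    abort_flav("`papp` must be finite and > 0 to take -log10.",
               class = "flavperm_domain_error")
  }
  -log10(papp)
}

#' @rdname papp_to_ppapp
#' @export
ppapp_to_papp <- function(ppapp) {
  if (any(!is.finite(ppapp))) {
    abort_flav("`ppapp` must be finite.", class = "flavperm_domain_error")
  }
  10^(-ppapp)
}
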