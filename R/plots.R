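# ggplot2 displays for the two result types: the fitted permeability
# model and the bidirectional transport summary.

#' Plot experimental versus predicted permeability
#'
#' Scatter of the experimental response against model predictions, with
#' the identity line.  Supply `newdata` (e.g. the test split) to overlay
#' held-out compounds; points are then coloured by the `split` column when
#' present.
#'
#' @param object A `qspr_model`.
#' @param newdata Optional extra data to predict and overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qspr_model <- function(object, newdata = NULL, ...) {
  df <- augment(object)
  df$split <- "training"
  if (!is.null(newdata)) {
    extra <- augment(object, newdata)
    if (!"split" %in% names(extra)) extra$split <- "test"
    df <- bind_rows(df, mutate(extra, split = as.character(.data$split)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.fitted,
                                   y = .data[[object$response]],
                                   colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Predicted pPapp (A to B)",
                  y = "Experimental pPapp (A to B)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bidirectional permeability by transport mechanism
#'
#' Absorptive against secretory Papp on log10 axes, coloured by the
#' mechanism class, with guide lines at the passive band and the efflux
#' cut-off.
#'
#' @param transport A transport summary from [transport_summary()].
#' @param bands Classification bands used for the guide lines.
#' @return A ggplot object.
#' @export
plot_transport <- function(transport, bands = transport_bands()) {
  check_columns(transport, c("papp_ab", "papp_ba", "mechanism"))
  ggplot2::ggplot(transport,
                  ggplot2::aes(x = .data$papp_ab * 1e6,
                               y = .data$papp_ba * 1e6,
                               colour = .data$mechanism)) +
    ggplot2::geom_abline(slope = 1, intercept = log10(c(bands$passive, bands$efflux)),
                         linetype = c(3, 3, 2), colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Papp A to B (1e-6 cm/s)",
                  y = "Papp B to A (1e-6 cm/s)", colour = "mechanism") +
    ggplot2::theme_minimal()
}
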