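# End-to-end analysis pipeline: load -> transport report -> stability
# report -> descriptor screening -> stepwise selection -> model fit ->
# LOO and external validation -> report bundle on disk.

pipeline_defaults <- function() {
  list(
    input = "fang2017",
    method = "ols",
    n_components = NULL,
    collinearity_threshold = 0.7,
    enter_p = 0.05,
    remove_p = 0.10,
    outlier_screen = FALSE,
    outlier_threshold = 0.600,
    recovery_gate = 60,
    passive_band = c(0.8, 1.5),
    efflux_cut = 2.0,
    absorptive_cut = 0.5,
    use_printed_ratio = FALSE,
    seed = 20171129
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_flav(sprintf("pipeline stage '%s' failed: %s", stage,
                       conditionMessage(e)),
               class = "flavperm_pipeline_error", parent = e)
  })
}

#' Run the full permeability analysis pipeline
#'
#' Loads a study (packaged fixture name or CSV directory), builds the
#' transport and stability reports, screens descriptors (correlation
#' matrix, collinearity filter, stepwise selection), fits the permeability
#' model, validates it by leave-one-out cross-validation and on the
#' external test split, and writes a report bundle to `out_dir`:
#' `transport_report.csv`, `stability_report.csv`,
#' `correlation_matrix.csv`, `qspr_report.csv`, `qspr_model.json`,
#' `validation.csv` and `run.log`.  All results are computed before
#' anything is written, so a failing stage leaves no partial outputs, and
#' every output is a deterministic function of the configuration and seed.
#'
#' Settings are resolved in order: package defaults, then the `config`
#' YAML file or list, then named arguments in `...`; later wins.
#' Available settings and defaults: `input` ("fang2017"), `method`
#' ("ols"), `n_components` (NULL), `collinearity_threshold` (0.7),
#' `enter_p` (0.05), `remove_p` (0.10), `outlier_screen` (FALSE, because
#' the packaged descriptor table is already post-screening),
#' `outlier_threshold` (0.600), `recovery_gate` (60), `passive_band`
#' (c(0.8, 1.5)), `efflux_cut` (2.0), `absorptive_cut` (0.5),
#' `use_printed_ratio` (FALSE), `seed` (20171129).
#'
#' @param out_dir Output directory for the report bundle.
#' @param config Optional YAML file path or named list of settings.
#' @param ... Named setting overrides; take precedence over `config`.
#' @return Invisibly, a list: `study`, `transport`, `stability`, `cormat`,
#'   `collinearity`, `selected`, `model`, `external`, `report`, `settings`.
#' @examples
#' \donttest{
#' res <- run_pipeline(out_dir = tempfile("flavperm-run-"))
#' glance(res$model)
#' }
#' @export
run_pipeline <- function(out_dir, config = NULL, ...) {
  settings <- pipeline_defaults()
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    settings <- modifyList(settings, config, keep.null = TRUE)
  }
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(settings))
    if (length(bad) > 0) {
      abort_flav(sprintf("unknown pipeline setting(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "flavperm_schema_error")
    }
    settings <- modifyList(settings, overrides, keep.null = TRUE)
  }
  bands <- transport_bands(passive = settings$passive_band,
                           efflux = settings$efflux_cut,
                           absorptive = settings$absorptive_cut)

  study <- run_stage("load", load_study(settings$input))
  transport <- run_stage("transport", transport_summary(
    study, bands = bands, use_printed_ratio = settings$use_printed_ratio))
  stability <- run_stage("stability", stability_summary(
    study, recovery_gate = settings$recovery_gate))

  qspr <- run_stage("qspr", {
    training <- filter(study$descriptors, .data$split == "training")
    test <- filter(study$descriptors, .data$split == "test")
    cormat <- correlation_matrix(training, "ppapp_exp")
    coll <- filter_collinear(cormat, threshold = settings$collinearity_threshold)
    selected <- stepwise_select(training, "ppapp_exp",
                                candidates = coll$retained,
                                enter_p = settings$enter_p,
                                remove_p = settings$remove_p)
    screen <- NULL
    if (isTRUE(settings$outlier_screen)) {
      screen <- screen_outliers(training, "ppapp_exp", as.character(selected),
                                residual_threshold = settings$outlier_threshold,
                                method = settings$method,
                                n_components = settings$n_components)
      training <- filter(training, !.data$compound_id %in% screen$excluded)
    }
    model <- qspr_fit(training, "ppapp_exp", as.character(selected),
                      method = settings$method,
                      n_components = settings$n_components)
    external <- validate_external(model, test)
    report <- bind_rows(
      augment(model, training) %>% mutate(split = "training"),
      augment(model, test) %>% mutate(split = "test")
    ) %>%
      select("compound_id", "split", "ppapp_exp",
             ppapp_pred = ".fitted", residual = ".resid",
             all_of(as.character(selected)))
    list(cormat = cormat, collinearity = coll, selected = selected,
         screen = screen, model = model, external = external,
         report = report)
  })

  # all stages succeeded; write the bundle
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(transport, file.path(out_dir, "transport_report.csv"))
  readr::write_csv(stability, file.path(out_dir, "stability_report.csv"))
  cor_df <- as.data.frame(unclass(qspr$cormat))
  readr::write_csv(cbind(variable = rownames(cor_df), cor_df),
                   file.path(out_dir, "correlation_matrix.csv"))
  readr::write_csv(qspr$report, file.path(out_dir, "qspr_report.csv"))
  qspr_model_to_json(qspr$model, file.path(out_dir, "qspr_model.json"))
  s <- qspr$model$stats
  readr::write_csv(tibble(
    n_train = s$n, r2 = s$r2, r2_adj = s$r2_adj, f_stat = s$f_stat,
    p_value = s$p_value, see = s$see, rmse_train = s$rmse, q2 = s$q2,
    press = s$press, n_test = qspr$external$n,
    r2_pred = qspr$external$r2_pred, rmse_test = qspr$external$rmse
  ), file.path(out_dir, "validation.csv"))

  log_lines <- c(
    sprintf("flavperm %s", as.character(packageVersion("flavperm"))),
    sprintf("config hash: %s", rlang::hash(settings)),
    sprintf("seed: %s", settings$seed),
    sprintf("input: %s", settings$input),
    sprintf("compounds: %d", nrow(study$compounds)),
    sprintf("efflux-implicated: %s",
            paste(transport$compound_id[transport$mechanism == "efflux_implicated"],
                  collapse = ", ")),
    sprintf("selected descriptors: %s",
            paste(qspr$selected, collapse = ", ")),
    sprintf("model: %s  R2 = %.3f  Q2 = %.3f  R2_pred = %.3f",
            settings$method, s$r2, s$q2, qspr$external$r2_pred)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(study = study, transport = transport, stability = stability,
                 cormat = qspr$cormat, collinearity = qspr$collinearity,
                 selected = qspr$selected, screen = qspr$screen,
                 model = qspr$model, external = qspr$external,
                 report = qspr$report, settings = settings))
}
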