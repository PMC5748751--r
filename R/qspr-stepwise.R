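#' Stepwise descriptor selection
#'
#' Forward selection with backward elimination on partial-F p-values, the
#' classic SPSS-style stepwise linear regression.  At each step the
#' candidate whose addition has the smallest partial-F p-value enters if
#' that p-value is below `enter_p`; after each entry, any previously
#' entered descriptor whose partial-F p-value has risen above `remove_p`
#' is removed again (the descriptor that just entered is exempt within the
#' same step).  For a single added term the partial F equals the square of
#' its t statistic, so the t-test p-value of the coefficient is used.
#' Ties are broken by the lowest p-value, then alphabetically, making the
#' procedure deterministic.
#'
#' Entry stops when no candidate passes `enter_p` or when another entry
#' would leave fewer than three residual degrees of freedom.
#'
#' @param data Data frame with the response and candidate columns.
#' @param response Response column name.
#' @param candidates Character vector of candidate descriptor names;
#'   defaults to the canonical descriptors present in `data`.
#' @param enter_p Entry threshold on the partial-F p-value, default 0.05.
#' @param remove_p Removal threshold, default 0.10. Must be >= `enter_p`.
#' @return Character vector of selected descriptors in entry order, with a
#'   `trace` attribute (tibble of step, action, term, p_value).  Errors
#'   with class `flavperm_empty_selection` if nothing passes entry.
#' @examples
#' study <- load_study("fang2017")
#' training <- dplyr::filter(study$descriptors, split == "training")
#' stepwise_select(training, "ppapp_exp")
#' @export
stepwise_select <- function(data, response,
                            candidates = intersect(descriptor_names,
                                                   names(data)),
                            enter_p = 0.05, remove_p = 0.10) {
  check_columns(data, c(response, candidates))
  stopifnot(enter_p > 0, remove_p >= enter_p)
  n <- nrow(data)
  selected <- character()
  trace <- tibble(step = integer(), action = character(),
                  term = character(), p_value = numeric())
  step <- 0L

  term_p <- function(terms, term) {
    fit <- lm(stats::reformulate(terms, response), data = data)
    # summary.lm warns on exact fits; a p-value of ~0 is the right answer
    suppressWarnings(summary(fit))$coefficients[term, 4]
  }

  repeat {
    remaining <- setdiff(candidates, selected)
    # another entry must keep n > (k + 1) + 2 residual-df guard
    if (length(remaining) == 0 || n <= length(selected) + 3) break
    ps <- vapply(remaining, function(v) term_p(c(selected, v), v), numeric(1))
    ord <- order(ps, remaining)
    if (ps[ord[1]] >= enter_p) break
    entered <- remaining[ord[1]]
    step <- step + 1L
    selected <- c(selected, entered)
    trace <- bind_rows(trace, tibble(step = step, action = "enter",
                                     term = entered, p_value = ps[ord[1]]))
    # backward pass over previously entered terms
    repeat {
      removable <- setdiff(selected, entered)
      if (length(removable) == 0) break
      rp <- vapply(removable, function(v) term_p(selected, v), numeric(1))
      ordr <- order(-rp, removable)
      if (rp[ordr[1]] <= remove_p) break
      victim <- removable[ordr[1]]
      selected <- setdiff(selected, victim)
      trace <- bind_rows(trace, tibble(step = step, action = "remove",
                                       term = victim, p_value = rp[ordr[1]]))
    }
  }

  if (length(selected) == 0) {
    abort_flav(sprintf("no descriptor passes the entry threshold (enter_p = %g)",
                       enter_p),
               class = "flavperm_empty_selection")
  }
  structure(selected, trace = trace)
}
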