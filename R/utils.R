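# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop with a classed condition so callers can test on class, not message
abort_flav <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "flavperm_error"), ...)
}

check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(x <= 0, na.rm = TRUE) else any(x < 0, na.rm = TRUE)
  if (any(!is.finite(x[!is.na(x)])) || bad) {
    abort_flav(
      sprintf("`%s` must be %s and finite.", name,
              if (strict) "> 0" else ">= 0"),
      class = "flavperm_domain_error"
    )
  }
  invisible(x)
}

check_columns <- function(data, cols, where = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_flav(
      sprintf("%s is missing required column(s): %s.", where,
              paste0("`", missing, "`", collapse = ", ")),
      class = "flavperm_schema_error"
    )
  }
  invisible(data)
}
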