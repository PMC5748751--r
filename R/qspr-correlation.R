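# Descriptor screening: Pearson correlation matrix and collinearity filter.

#' Pearson correlation matrix of response and descriptors
#'
#' Pairwise Pearson coefficients among the modelling response and the
#' molecular descriptors, the standard first look before descriptor
#' selection: the response row shows which descriptors carry signal, the
#' descriptor block shows which are mutually collinear.
#'
#' @param data A data frame with one row per compound.
#' @param response Name of the response column.
#' @param descriptors Character vector of descriptor columns; defaults to
#'   the four canonical descriptors present in `data`.
#' @return A symmetric correlation matrix of class `flav_cormat` with the
#'   response as its first row/column.
#' @examples
#' study <- load_study("fang2017")
#' training <- dplyr::filter(study$descriptors, split == "training")
#' correlation_matrix(training, "ppapp_exp")
#' @export
correlation_matrix <- function(data, response,
                               descriptors = intersect(descriptor_names,
                                                       names(data))) {
  vars <- c(response, descriptors)
  check_columns(data, vars)
  m <- as.matrix(data[vars])
  if (nrow(m) < 3) {
    abort_flav("need at least 3 compounds to correlate",
               class = "flavperm_insufficient_data")
  }
  if (anyNA(m)) {
    abort_flav("correlation_matrix() requires complete cases",
               class = "flavperm_domain_error")
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort_flav(sprintf("column `%s` is constant; its correlation is undefined",
                       vars[sds == 0][1]),
               class = "flavperm_domain_error")
  }
  out <- cor(m)
  structure(out, class = c("flav_cormat", class(out)), response = response)
}

#' @export
print.flav_cormat <- function(x, digits = 3, ...) {
  cat("<flav_cormat> response:", attr(x, "response"), "\n")
  y <- x
  attr(y, "response") <- NULL
  print(round(unclass(y), digits), ...)
  invisible(x)
}

#' Drop collinear descriptors
#'
#' Greedy collinearity filter: while any pair of descriptors correlates
#' beyond `threshold` in absolute value, the pair with the largest
#' inter-correlation is examined and the member with the weaker absolute
#' correlation to the response is dropped (ties broken by dropping the
#' alphabetically later name).  Repeats until no violation remains.
#'
#' @param cmat A `flav_cormat` from [correlation_matrix()].
#' @param threshold Absolute inter-descriptor correlation above which one
#'   member of a pair is dropped. Default 0.7.
#' @return A list with `retained` (character vector, original order) and
#'   `dropped` (tibble with columns `dropped`, `kept`, `r`).
#' @export
filter_collinear <- function(cmat, threshold = 0.7) {
  stopifnot(inherits(cmat, "flav_cormat"), threshold > 0)
  response <- attr(cmat, "response")
  desc <- setdiff(rownames(cmat), response)
  dropped <- tibble(dropped = character(), kept = character(), r = numeric())
  repeat {
    if (length(desc) < 2) break
    block <- abs(cmat[desc, desc, drop = FALSE])
    diag(block) <- 0
    if (max(block) <= threshold) break
    idx <- which(block == max(block), arr.ind = TRUE)[1, ]
    pair <- sort(c(desc[idx[1]], desc[idx[2]]))
    to_resp <- abs(cmat[pair, response])
    # drop the weaker-to-response member; alphabetically later on ties
    victim <- if (to_resp[1] < to_resp[2]) pair[1]
              else if (to_resp[2] < to_resp[1]) pair[2]
              else pair[2]
    dropped <- bind_rows(dropped, tibble(
      dropped = victim, kept = setdiff(pair, victim),
      r = cmat[pair[1], pair[2]]
    ))
    desc <- setdiff(desc, victim)
  }
  list(retained = desc, dropped = dropped)
}
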