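# Study container: five cross-linked per-compound tables
#   compounds    - identity, subclass, substituent map, glycoside flag
#   transport    - bidirectional Papp (stored in cm/s) + printed efflux ratio
#   accumulation - cellular accumulation per direction (umol/g) with ND/NT codes
#   stability    - relative concentration (%) and mass-balance recovery (%)
#   descriptors  - molecular descriptors + experimental/predicted pPapp + split

flav_subclasses <- c("flavone", "flavonol", "flavanone", "isoflavone",
                     "chalcone", "dihydrochalcone")
glycosyl_codes <- c("Cglc", "Carb", "Orha", "ORG", "ONG", "NG")
substituent_cols <- c("R3", "R5", "R6", "R7", "R8", "R2p", "R3p", "R4p", "R5p")
descriptor_names <- c("QC3p", "E_sol", "SlogP_V3", "vsurf_ID1")
direction_levels <- c("ns", "p<0.05", "p<0.01", "unevaluable")

# ---- low-level CSV parsing ------------------------------------------------

read_raw_table <- function(path, expected_cols) {
  if (!file.exists(path)) {
    abort_flav(sprintf("missing file: '%s'", path),
               class = "flavperm_io_error")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  fields <- if (length(header) == 0) character() else strsplit(header, ",")[[1]]
  if (!identical(trimws(fields), expected_cols)) {
    abort_flav(
      sprintf("malformed header in '%s': expected columns %s", basename(path),
              paste(expected_cols, collapse = ", ")),
      class = "flavperm_schema_error"
    )
  }
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  as_tibble(out)
}

# numeric column that may carry missing-data codes; anything else is an error
parse_numeric <- function(x, file, col, codes = c("ND", "NT", "-")) {
  x <- trimws(x)
  is_code <- x %in% codes | x == ""
  val <- suppressWarnings(as.numeric(x))
  bad <- !is_code & is.na(val)
  if (any(bad)) {
    abort_flav(
      sprintf("non-numeric cell '%s' in column `%s` of %s (only %s mark missing values)",
              x[bad][1], col, file, paste(codes, collapse = "/")),
      class = "flavperm_parse_error"
    )
  }
  val[is_code] <- NA_real_
  code <- ifelse(x %in% c("ND", "NT"), x, NA_character_)
  list(value = val, code = code)
}

parse_id <- function(x, file) {
  p <- parse_numeric(x, file, "id", codes = character())
  id <- as.integer(p$value)
  if (anyDuplicated(id)) {
    abort_flav(sprintf("duplicate compound_id %s in %s",
                       id[duplicated(id)][1], file),
               class = "flavperm_schema_error")
  }
  id
}

# ---- loading --------------------------------------------------------------

#' Load a permeability study dataset
#'
#' Reads the five per-compound CSV tables of a flavonoid transport study
#' (compounds, transport, accumulation, stability, descriptors) and returns
#' them as a cross-linked `flav_study` object.  `source` may be the name of a
#' packaged dataset (currently `"fang2017"`, the 30-compound Caco-2 study
#' shipped with the package) or a directory containing the five CSV files.
#'
#' File-level conventions: Papp values are stored in the files in units of
#' 1e-6 cm/s (the scale on which such tables are printed) and converted to
#' cm/s on load; `ND` (not detected) and `NT` (not tested) mark missing
#' measurements and are preserved as missing-value codes, never as zeros;
#' `-` marks a value that was not reported.
#'
#' @param source Packaged dataset name or path to a directory of CSV files.
#'
#' @return A `flav_study`: a named list of tibbles `compounds`, `transport`,
#'   `accumulation`, `stability`, `descriptors`, each keyed by `compound_id`.
#'
#' @examples
#' study <- load_study("fang2017")
#' study$transport
#' @export
load_study <- function(source = "fang2017") {
  dir <- source
  if (!dir.exists(source)) {
    pkg_dir <- system.file("extdata", source, package = "flavperm")
    if (!nzchar(pkg_dir)) {
      abort_flav(sprintf("missing file: '%s' is neither a directory nor a packaged dataset",
                         source),
                 class = "flavperm_io_error")
    }
    dir <- pkg_dir
  }

  compounds <- read_compounds(file.path(dir, "compounds.csv"))
  transport <- read_transport(file.path(dir, "transport.csv"))
  accumulation <- read_accumulation(file.path(dir, "accumulation.csv"))
  stability <- read_stability(file.path(dir, "stability.csv"))
  descriptors <- read_descriptors(file.path(dir, "descriptors.csv"))

  study <- structure(
    list(compounds = compounds, transport = transport,
         accumulation = accumulation, stability = stability,
         descriptors = descriptors),
    class = "flav_study"
  )
  validate_study(study)
}

read_compounds <- function(path) {
  cols <- c("id", "name", "subclass", substituent_cols, "is_glycoside")
  raw <- read_raw_table(path, cols)
  id <- parse_id(raw$id, "compounds.csv")
  bad <- setdiff(unique(raw$subclass), flav_subclasses)
  if (length(bad) > 0) {
    abort_flav(sprintf("unknown subclass '%s' in compounds.csv", bad[1]),
               class = "flavperm_parse_error")
  }
  tibble(
    compound_id = id,
    name = raw$name,
    subclass = factor(raw$subclass, levels = flav_subclasses),
    !!!raw[substituent_cols],
    is_glycoside = as.logical(raw$is_glycoside)
  )
}

read_transport <- function(path) {
  cols <- c("id", "papp_ab_mean", "papp_ab_sd", "papp_ba_mean", "papp_ba_sd",
            "ratio_p")
  raw <- read_raw_table(path, cols)
  id <- parse_id(raw$id, "transport.csv")
  num <- lapply(cols[-1], function(cl) {
    parse_numeric(raw[[cl]], "transport.csv", cl)$value
  })
  names(num) <- cols[-1]
  tibble(
    compound_id = id,
    papp_ab = num$papp_ab_mean * 1e-6,
    papp_ab_sd = num$papp_ab_sd * 1e-6,
    papp_ba = num$papp_ba_mean * 1e-6,
    papp_ba_sd = num$papp_ba_sd * 1e-6,
    ratio_p = num$ratio_p
  )
}

read_accumulation <- function(path) {
  cols <- c("id", "ca_ab_mean", "ca_ab_sd", "ca_ba_mean", "ca_ba_sd",
            "ratio_c", "direction_diff")
  raw <- read_raw_table(path, cols)
  id <- parse_id(raw$id, "accumulation.csv")
  ab <- parse_numeric(raw$ca_ab_mean, "accumulation.csv", "ca_ab_mean")
  ab_sd <- parse_numeric(raw$ca_ab_sd, "accumulation.csv", "ca_ab_sd")
  ba <- parse_numeric(raw$ca_ba_mean, "accumulation.csv", "ca_ba_mean")
  ba_sd <- parse_numeric(raw$ca_ba_sd, "accumulation.csv", "ca_ba_sd")
  rc <- parse_numeric(raw$ratio_c, "accumulation.csv", "ratio_c")
  dd <- trimws(raw$direction_diff)
  bad <- setdiff(unique(dd), direction_levels)
  if (length(bad) > 0) {
    abort_flav(sprintf("unknown direction_diff flag '%s' in accumulation.csv",
                       bad[1]),
               class = "flavperm_parse_error")
  }
  tibble(
    compound_id = id,
    ca_ab = ab$value, ca_ab_sd = ab_sd$value, ca_ab_code = ab$code,
    ca_ba = ba$value, ca_ba_sd = ba_sd$value, ca_ba_code = ba$code,
    ratio_c = rc$value,
    direction_diff = factor(dd, levels = direction_levels)
  )
}

read_stability <- function(path) {
  cols <- c("id", "rel_conc", "recovery_ba_mean", "recovery_ba_sd", "rsd_ba",
            "recovery_ab_mean", "recovery_ab_sd", "rsd_ab")
  raw <- read_raw_table(path, cols)
  id <- parse_id(raw$id, "stability.csv")
  rc <- parse_numeric(raw$rel_conc, "stability.csv", "rel_conc")
  num <- lapply(cols[-(1:2)], function(cl) {
    parse_numeric(raw[[cl]], "stability.csv", cl)$value
  })
  names(num) <- cols[-(1:2)]
  tibble(
    compound_id = id,
    rel_conc = rc$value,
    rel_conc_code = rc$code,
    recovery_ba = num$recovery_ba_mean, recovery_ba_sd = num$recovery_ba_sd,
    rsd_ba = num$rsd_ba,
    recovery_ab = num$recovery_ab_mean, recovery_ab_sd = num$recovery_ab_sd,
    rsd_ab = num$rsd_ab
  )
}

read_descriptors <- function(path) {
  cols <- c("id", "split", "ppapp_exp", "ppapp_pred", "E_sol", "SlogP_V3",
            "QC3p", "vsurf_ID1", "residual")
  raw <- read_raw_table(path, cols)
  id <- parse_id(raw$id, "descriptors.csv")
  splits <- c("training", "test", "excluded")
  bad <- setdiff(unique(raw$split), splits)
  if (length(bad) > 0) {
    abort_flav(sprintf("unknown split '%s' in descriptors.csv", bad[1]),
               class = "flavperm_parse_error")
  }
  num <- lapply(cols[-(1:2)], function(cl) {
    parse_numeric(raw[[cl]], "descriptors.csv", cl)$value
  })
  names(num) <- cols[-(1:2)]
  tibble(
    compound_id = id,
    split = factor(raw$split, levels = splits),
    ppapp_exp = num$ppapp_exp,
    ppapp_pred = num$ppapp_pred,
    QC3p = num$QC3p, E_sol = num$E_sol,
    SlogP_V3 = num$SlogP_V3, vsurf_ID1 = num$vsurf_ID1,
    residual = num$residual
  )
}

# ---- cross-table validation ----------------------------------------------

validate_study <- function(study) {
  ids <- study$compounds$compound_id
  for (tbl in c("transport", "accumulation", "stability", "descriptors")) {
    unknown <- setdiff(study[[tbl]]$compound_id, ids)
    if (length(unknown) > 0) {
      abort_flav(sprintf("unknown compound_id %s in %s table", unknown[1], tbl),
                 class = "flavperm_schema_error")
    }
  }
  # glycoside flag must agree with the substituent map
  sub <- as.matrix(study$compounds[substituent_cols])
  has_gly <- apply(sub, 1L, function(r) any(r %in% glycosyl_codes))
  if (!identical(unname(has_gly), study$compounds$is_glycoside)) {
    off <- ids[has_gly != study$compounds$is_glycoside][1]
    abort_flav(
      sprintf("is_glycoside flag of compound %s disagrees with its substituent map", off),
      class = "flavperm_schema_error"
    )
  }
  check_positive(study$transport$papp_ab, "papp_ab", strict = FALSE)
  check_positive(study$transport$papp_ba, "papp_ba", strict = FALSE)
  study
}

#' @export
print.flav_study <- function(x, ...) {
  cat("<flav_study> ", nrow(x$compounds), " compounds\n", sep = "")
  cat("  transport:    ", nrow(x$transport), " compounds (bidirectional Papp)\n", sep = "")
  cat("  accumulation: ", sum(!is.na(x$accumulation$ca_ab)),
      " measured / ", nrow(x$accumulation), " compounds\n", sep = "")
  cat("  stability:    ", nrow(x$stability), " compounds\n", sep = "")
  n_tr <- sum(x$descriptors$split == "training")
  n_te <- sum(x$descriptors$split == "test")
  cat("  descriptors:  ", nrow(x$descriptors), " compounds (",
      n_tr, " training / ", n_te, " test)\n", sep = "")
  invisible(x)
}

# ---- writing --------------------------------------------------------------

fmt_cell <- function(value, code = NULL) {
  out <- ifelse(is.na(value), "-", vapply(value, function(v) {
    if (is.na(v)) "-" else as.character(v)
  }, character(1)))
  if (!is.null(code)) out <- ifelse(!is.na(code), code, out)
  out
}

#' Write a study dataset to a directory of CSV files
#'
#' Inverse of [load_study()]: writes the five study tables using the same
#' schemas the loader reads, so `load_study(write_study(study, dir))` round
#' trips.  Papp columns are written in display units of 1e-6 cm/s; missing
#' measurements keep their `ND`/`NT` codes and unreported cells are `-`.
#'
#' @param study A `flav_study` object.
#' @param dir Output directory; created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "flav_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- study$compounds
  readr::write_csv(tibble(
    id = co$compound_id, name = co$name, subclass = as.character(co$subclass),
    !!!co[substituent_cols], is_glycoside = co$is_glycoside
  ), file.path(dir, "compounds.csv"))

  tr <- study$transport
  readr::write_csv(tibble(
    id = tr$compound_id,
    papp_ab_mean = tr$papp_ab / 1e-6, papp_ab_sd = tr$papp_ab_sd / 1e-6,
    papp_ba_mean = tr$papp_ba / 1e-6, papp_ba_sd = tr$papp_ba_sd / 1e-6,
    ratio_p = tr$ratio_p
  ), file.path(dir, "transport.csv"))

  ac <- study$accumulation
  readr::write_csv(tibble(
    id = ac$compound_id,
    ca_ab_mean = fmt_cell(ac$ca_ab, ac$ca_ab_code),
    ca_ab_sd = fmt_cell(ac$ca_ab_sd, ac$ca_ab_code),
    ca_ba_mean = fmt_cell(ac$ca_ba, ac$ca_ba_code),
    ca_ba_sd = fmt_cell(ac$ca_ba_sd, ac$ca_ba_code),
    ratio_c = fmt_cell(ac$ratio_c),
    direction_diff = as.character(ac$direction_diff)
  ), file.path(dir, "accumulation.csv"))

  st <- study$stability
  readr::write_csv(tibble(
    id = st$compound_id,
    rel_conc = fmt_cell(st$rel_conc, st$rel_conc_code),
    recovery_ba_mean = fmt_cell(st$recovery_ba),
    recovery_ba_sd = fmt_cell(st$recovery_ba_sd),
    rsd_ba = fmt_cell(st$rsd_ba),
    recovery_ab_mean = fmt_cell(st$recovery_ab),
    recovery_ab_sd = fmt_cell(st$recovery_ab_sd),
    rsd_ab = fmt_cell(st$rsd_ab)
  ), file.path(dir, "stability.csv"))

  de <- study$descriptors
  readr::write_csv(tibble(
    id = de$compound_id, split = as.character(de$split),
    ppapp_exp = fmt_cell(de$ppapp_exp), ppapp_pred = fmt_cell(de$ppapp_pred),
    E_sol = fmt_cell(de$E_sol), SlogP_V3 = fmt_cell(de$SlogP_V3),
    QC3p = fmt_cell(de$QC3p), vsurf_ID1 = fmt_cell(de$vsurf_ID1),
    residual = fmt_cell(de$residual)
  ), file.path(dir, "descriptors.csv"))

  invisible(dir)
}

#' Serialize a study dataset to and from JSON
#'
#' @param study A `flav_study` object.
#' @param path JSON file path.
#' @return `study_to_json()` returns `path` invisibly; `study_from_json()`
#'   returns a `flav_study`.
#' @export
study_to_json <- function(study, path) {
  stopifnot(inherits(study, "flav_study"))
  plain <- lapply(unclass(study), function(tbl) {
    tbl <- as.data.frame(tbl)
    tbl[] <- lapply(tbl, function(col) if (is.factor(col)) as.character(col) else col)
    tbl
  })
  jsonlite::write_json(plain, path, dataframe = "columns", digits = NA,
                       na = "null", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname study_to_json
#' @export
study_from_json <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  study <- lapply(plain, as_tibble)
  study$compounds$subclass <- factor(study$compounds$subclass,
                                     levels = flav_subclasses)
  study$accumulation$direction_diff <- factor(study$accumulation$direction_diff,
                                              levels = direction_levels)
  study$descriptors$split <- factor(study$descriptors$split,
                                    levels = c("training", "test", "excluded"))
  # columns that are all-missing deserialize as logical; restore types
  for (tbl in names(study)) {
    nm <- names(study[[tbl]])
    study[[tbl]][] <- lapply(seq_along(nm), function(i) {
      col <- study[[tbl]][[i]]
      if (endsWith(nm[i], "_code")) as.character(col)
      else if (is.logical(col) && all(is.na(col)) && nm[i] != "is_glycoside") as.numeric(col)
      else col
    })
  }
  validate_study(structure(study, class = "flav_study"))
}
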