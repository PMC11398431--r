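# Config-file loaders: vocabularies, cohort criteria, outlier ranges and
# generator settings are data, not code, so sites exchange them as files.

read_config_list <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("Reading YAML configs requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  } else {
    rlang::abort("Config files must be .json, .yaml or .yml.")
  }
}

#' Read controlled vocabularies from a config file
#'
#' The file maps element names to objects with a `permitted` array and an
#' optional `mapping` object (source name to category), e.g.
#' `{"lab_category": {"permitted": ["hemoglobin"], "mapping":
#' {"UCM_LAB HEMOGLOBIN - AUTOMATED": "hemoglobin"}}}`. Elements present in
#' the file replace the package defaults; all other defaults are retained.
#'
#' @param path JSON or YAML file.
#' @param base Vocabulary list to extend, by default [clif_vocabularies()].
#' @return Named list of [clif_vocabulary] objects.
#' @export
read_vocabularies <- function(path, base = clif_vocabularies()) {
  raw <- read_config_list(path)
  for (element in names(raw)) {
    entry <- raw[[element]]
    base[[element]] <- clif_vocabulary(
      element,
      permitted = unlist(entry$permitted),
      mapping = unlist(entry$mapping %||% list())
    )
  }
  base
}

#' Read cohort criteria from a config file
#'
#' Recognized keys: `min_age_years`, `max_icu_entry_offset_hours`,
#' `min_icu_stay_hours`, `window` (length-2 dates). Missing keys keep the
#' consortium defaults.
#'
#' @param path JSON or YAML file.
#' @return A [cohort_criteria()] object.
#' @export
read_cohort_criteria <- function(path) {
  raw <- read_config_list(path)
  known <- c("min_age_years", "max_icu_entry_offset_hours",
             "min_icu_stay_hours", "window")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown criteria key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(cohort_criteria, raw)
}

#' Read an outlier-range table from CSV
#'
#' Expects the columns of [default_outlier_ranges()]: `stream`, `category`,
#' `min_plausible`, `max_plausible`, `unit`.
#'
#' @param path CSV file.
#' @return A tibble usable with [apply_outlier_ranges()].
#' @export
read_outlier_ranges <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("stream", "category", "min_plausible", "max_plausible")
  missing_cols <- setdiff(needed, names(r))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Outlier-range file is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(r$min_plausible >= r$max_plausible)) {
    rlang::abort("Every outlier range needs min_plausible < max_plausible.")
  }
  if (anyDuplicated(r[, c("stream", "category")])) {
    rlang::abort("One row per (stream, category) is required.")
  }
  r
}

#' Read generator settings from a config file
#'
#' Keys are the arguments of [synth_config()]; missing keys keep the
#' defaults. Nested outcome models (`mortality`, `ventilation`) may be given
#' partially; their `subphenotype` vectors must be named NT/HT/HFR/HSR.
#'
#' @param path JSON or YAML file.
#' @return A [synth_config()] object.
#' @export
read_synth_config <- function(path) {
  raw <- read_config_list(path)
  for (fld in c("race_probs", "ethnicity_probs", "subphenotype_weights")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  for (fld in c("mortality", "ventilation")) {
    if (!is.null(raw[[fld]]$subphenotype)) {
      raw[[fld]]$subphenotype <- unlist(raw[[fld]]$subphenotype)
    }
  }
  do.call(synth_config, raw)
}
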