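#' ICU cohort inclusion criteria
#'
#' The consortium cohort definition: all adults (at least `min_age_years`
#' at admission) admitted to an ICU within `max_icu_entry_offset_hours` of
#' hospital admission and staying in the ICU at least `min_icu_stay_hours`,
#' with the hospital admission date inside `window`. All boundaries are
#' inclusive ("within 48 hours", "at least 24 hours", ">= 18 years").
#'
#' @param min_age_years Minimum age at admission (default 18).
#' @param max_icu_entry_offset_hours Maximum hospital-admission to ICU-entry
#'   offset (default 48).
#' @param min_icu_stay_hours Minimum contiguous ICU time from first ICU entry
#'   (default 24).
#' @param window Length-2 Date/character vector of admission dates (default
#'   the 2020--2021 study window).
#' @return A list of class `clif_cohort_criteria`.
#' @export
cohort_criteria <- function(min_age_years = 18,
                            max_icu_entry_offset_hours = 48,
                            min_icu_stay_hours = 24,
                            window = c("2020-01-01", "2021-12-31")) {
  stopifnot(min_age_years > 0, max_icu_entry_offset_hours > 0, min_icu_stay_hours > 0)
  window <- as.Date(window)
  if (window[1] > window[2]) rlang::abort("Criteria window start is after its end.")
  structure(
    list(min_age_years = min_age_years,
         max_icu_entry_offset_hours = max_icu_entry_offset_hours,
         min_icu_stay_hours = min_icu_stay_hours,
         window = window),
    class = "clif_cohort_criteria"
  )
}

# Merge back-to-back ICU ADT segments separated by less than `gap_hours`
# (transfer artifacts), then return the first merged block per encounter.
first_icu_block <- function(adt, gap_hours = 1) {
  icu <- adt[!is.na(adt$location_category) &
               norm_category(adt$location_category) == "icu", ]
  if (nrow(icu) == 0) {
    return(tibble::tibble(hospitalization_id = character(0),
                          icu_entry_dttm = as.POSIXct(character(0), tz = "UTC"),
                          icu_exit_dttm = as.POSIXct(character(0), tz = "UTC")))
  }
  icu <- dplyr::arrange(icu, .data$hospitalization_id, .data$in_dttm)
  icu %>%
    dplyr::group_by(.data$hospitalization_id) %>%
    dplyr::mutate(
      gap_h = as.numeric(difftime(.data$in_dttm, dplyr::lag(cummax_dttm(.data$out_dttm)),
                                  units = "hours")),
      new_block = dplyr::if_else(is.na(.data$gap_h) | .data$gap_h < gap_hours, 0L, 1L),
      block = cumsum(.data$new_block)
    ) %>%
    dplyr::filter(.data$block == 0L) %>%
    dplyr::summarise(
      icu_entry_dttm = min(.data$in_dttm),
      icu_exit_dttm = max(.data$out_dttm),
      .groups = "drop"
    )
}

# Running maximum for POSIXct (cummax drops the class).
cummax_dttm <- function(x) {
  as.POSIXct(cummax(as.numeric(x)), tz = "UTC", origin = "1970-01-01")
}

#' Discover the ICU cohort from ADT, hospitalization and patient tables
#'
#' An encounter qualifies iff (i) age at admission meets the minimum,
#' (ii) the first ICU ADT segment starts no later than the offset limit after
#' the hospital admission datetime, (iii) contiguous ICU time from first ICU
#' entry (merging back-to-back ICU segments separated by under an hour) meets
#' the minimum stay, and (iv) the hospital admission date falls inside the
#' window. Encounters with no ADT rows are skipped with a warning.
#'
#' @param dataset A validated [clif_dataset] with `adt`, `hospitalization`,
#'   and `patient` tables.
#' @param criteria A [cohort_criteria()].
#' @return A tibble of cohort members: `hospitalization_id`, `patient_id`,
#'   `icu_entry_dttm`, `icu_exit_dttm`, `age_at_admission`, demographic
#'   categories, `in_hospital_death`, and `ever_imv`.
#' @export
discover_icu_cohort <- function(dataset, criteria = cohort_criteria()) {
  stopifnot(inherits(dataset, "clif_dataset"), inherits(criteria, "clif_cohort_criteria"))
  needed <- c("adt", "hospitalization", "patient")
  absent <- setdiff(needed, names(dataset$tables))
  if (length(absent) > 0) {
    rlang::abort(sprintf("Cohort discovery needs table(s): %s", paste(absent, collapse = ", ")))
  }
  hosp <- dataset$tables$hospitalization
  no_adt <- setdiff(hosp$hospitalization_id, dataset$tables$adt$hospitalization_id)
  if (length(no_adt) > 0) {
    rlang::warn(sprintf("%d encounter(s) have no ADT rows and were skipped.", length(no_adt)))
  }
  blocks <- first_icu_block(dataset$tables$adt)

  ever_imv_ids <- character(0)
  if ("respiratory_support" %in% names(dataset$tables)) {
    rs <- dataset$tables$respiratory_support
    ever_imv_ids <- unique(rs$hospitalization_id[
      !is.na(rs$device_category) & norm_category(rs$device_category) == "imv"
    ])
  }

  members <- hosp %>%
    dplyr::inner_join(blocks, by = "hospitalization_id") %>%
    dplyr::left_join(dataset$tables$patient, by = "patient_id") %>%
    dplyr::mutate(
      entry_offset_h = as.numeric(difftime(.data$icu_entry_dttm, .data$admission_dttm,
                                           units = "hours")),
      icu_stay_h = as.numeric(difftime(.data$icu_exit_dttm, .data$icu_entry_dttm,
                                       units = "hours")),
      admission_date = as.Date(.data$admission_dttm)
    ) %>%
    dplyr::filter(
      .data$age_at_admission >= criteria$min_age_years,
      .data$entry_offset_h <= criteria$max_icu_entry_offset_hours,
      .data$icu_stay_h >= criteria$min_icu_stay_hours,
      .data$admission_date >= criteria$window[1],
      .data$admission_date <= criteria$window[2]
    ) %>%
    dplyr::transmute(
      hospitalization_id = .data$hospitalization_id,
      patient_id = .data$patient_id,
      icu_entry_dttm = .data$icu_entry_dttm,
      icu_exit_dttm = .data$icu_exit_dttm,
      age_at_admission = .data$age_at_admission,
      sex_category = norm_category(.data$sex_category),
      race_category = norm_category(.data$race_category),
      ethnicity_category = norm_category(.data$ethnicity_category),
      in_hospital_death = !is.na(.data$discharge_category) &
        norm_category(.data$discharge_category) == "expired",
      ever_imv = .data$hospitalization_id %in% ever_imv_ids
    )
  members
}

#' Consortium default plausibility ranges for vitals and labs
#'
#' Each row gives the plausible physiologic range for one (stream, category):
#' values outside it are treated as data entry errors (the canonical example
#' being a heart rate of 1,000 beats per minute). These defaults are artifact
#' defaults shipped with the package — the consortium's own table is not
#' public — and are fully overridable by passing any data frame with the same
#' columns to [apply_outlier_ranges()].
#'
#' @return A tibble with columns `stream`, `category`, `min_plausible`,
#'   `max_plausible`, `unit`.
#' @export
default_outlier_ranges <- function() {
  tribble_rows <- list(
    c("vitals", "temp_c", 25, 45, "degC"),
    c("vitals", "temp_f", 77, 113, "degF"),
    c("vitals", "heart_rate", 20, 300, "bpm"),
    c("vitals", "sbp", 30, 300, "mmHg"),
    c("vitals", "dbp", 10, 200, "mmHg"),
    c("vitals", "map", 20, 250, "mmHg"),
    c("vitals", "spo2", 50, 100, "%"),
    c("vitals", "respiratory_rate", 2, 80, "breaths/min"),
    c("vitals", "weight_kg", 20, 400, "kg"),
    c("vitals", "height_cm", 100, 250, "cm"),
    c("labs", "hemoglobin", 2, 25, "g/dL"),
    c("labs", "albumin", 0.5, 7, "g/dL"),
    c("labs", "ast", 5, 8000, "U/L"),
    c("labs", "alt", 5, 8000, "U/L"),
    c("labs", "creatinine", 0.1, 25, "mg/dL"),
    c("labs", "bun", 1, 250, "mg/dL"),
    c("labs", "sodium", 100, 185, "mmol/L"),
    c("labs", "potassium", 1, 12, "mmol/L"),
    c("labs", "chloride", 60, 150, "mmol/L"),
    c("labs", "bicarbonate", 2, 60, "mmol/L"),
    c("labs", "glucose", 10, 2000, "mg/dL"),
    c("labs", "wbc", 0.1, 200, "10^3/uL"),
    c("labs", "platelet_count", 1, 2000, "10^3/uL"),
    c("labs", "lactate", 0.1, 40, "mmol/L"),
    c("labs", "bilirubin_total", 0.1, 60, "mg/dL")
  )
  out <- tibble::tibble(
    stream = vapply(tribble_rows, `[`, character(1), 1),
    category = vapply(tribble_rows, `[`, character(1), 2),
    min_plausible = as.numeric(vapply(tribble_rows, `[`, character(1), 3)),
    max_plausible = as.numeric(vapply(tribble_rows, `[`, character(1), 4)),
    unit = vapply(tribble_rows, `[`, character(1), 5)
  )
  stopifnot(all(out$min_plausible < out$max_plausible),
            !anyDuplicated(out[, c("stream", "category")]))
  out
}

#' Set implausible vitals/labs values to missing
#'
#' Consortium-style outlier handling: any value outside its category's
#' plausible range is set to missing — the row is retained, so record counts
#' are preserved — and removals are counted per (stream, category). The
#' operation is idempotent.
#'
#' @param dataset A [clif_dataset].
#' @param ranges A plausibility-range table, by default
#'   [default_outlier_ranges()].
#' @return A list with `dataset` (cleaned) and `report` (tibble of
#'   `stream`, `category`, `n_removed`).
#' @export
apply_outlier_ranges <- function(dataset, ranges = default_outlier_ranges()) {
  stopifnot(inherits(dataset, "clif_dataset"))
  locs <- list(
    vitals = list(cat = "vital_category", val = "vital_value"),
    labs = list(cat = "lab_category", val = "lab_value_numeric")
  )
  report <- list()
  for (stream in names(locs)) {
    if (!stream %in% names(dataset$tables)) next
    df <- dataset$tables[[stream]]
    loc <- locs[[stream]]
    r <- ranges[ranges$stream == stream, ]
    m <- match(norm_category(df[[loc$cat]]), r$category)
    val <- df[[loc$val]]
    out_of_range <- !is.na(m) & !is.na(val) &
      (val < r$min_plausible[m] | val > r$max_plausible[m])
    if (any(out_of_range)) {
      df[[loc$val]][out_of_range] <- NA_real_
      dataset$tables[[stream]] <- df
    }
    removed <- table(df[[loc$cat]][out_of_range])
    report[[stream]] <- tibble::tibble(
      stream = stream,
      category = names(removed),
      n_removed = as.integer(removed)
    )
  }
  report <- dplyr::bind_rows(report)
  if (nrow(report) == 0) {
    report <- tibble::tibble(stream = character(0), category = character(0),
                             n_removed = integer(0))
  }
  list(dataset = dataset, report = report)
}
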