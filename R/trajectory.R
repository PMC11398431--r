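#' Build standardized 72-hour temperature series
#'
#' For each cohort encounter, takes temperature vitals recorded in
#' `[icu_entry, icu_entry + 72 h]`, converts Fahrenheit-labelled values
#' (`vital_category == "temp_f"`) to Celsius via `C = (F - 32) * 5/9`, and
#' bins readings to integer hours from ICU entry by the within-hour mean.
#' Encounters with zero temperature observations are excluded with the
#' reason recorded — the only exclusion the analysis makes.
#'
#' @param dataset A [clif_dataset], already cleaned of outliers.
#' @param cohort Cohort tibble from [discover_icu_cohort()].
#' @return A list with `series` (long tibble: `hospitalization_id`, `hour`
#'   0..72, `temp_c`) and `exclusions` (tibble: `hospitalization_id`,
#'   `reason`).
#' @export
build_temperature_series <- function(dataset, cohort) {
  stopifnot(inherits(dataset, "clif_dataset"))
  vit <- dataset$tables$vitals
  if (is.null(vit)) rlang::abort("Dataset has no vitals table.")
  temp <- vit[!is.na(vit$vital_category) &
                norm_category(vit$vital_category) %in% c("temp_c", "temp_f"), ]
  temp$temp_c <- ifelse(norm_category(temp$vital_category) == "temp_f",
                        (temp$vital_value - 32) * 5 / 9, temp$vital_value)
  series <- temp %>%
    dplyr::inner_join(cohort[, c("hospitalization_id", "icu_entry_dttm")],
                      by = "hospitalization_id") %>%
    dplyr::mutate(h = as.numeric(difftime(.data$recorded_dttm, .data$icu_entry_dttm,
                                          units = "hours"))) %>%
    dplyr::filter(.data$h >= 0, .data$h <= 72, !is.na(.data$temp_c)) %>%
    dplyr::mutate(hour = pmin(floor(.data$h), 72)) %>%
    dplyr::group_by(.data$hospitalization_id, .data$hour) %>%
    dplyr::summarise(temp_c = mean(.data$temp_c), .groups = "drop")

  excluded_ids <- setdiff(cohort$hospitalization_id, unique(series$hospitalization_id))
  list(
    series = series,
    exclusions = tibble::tibble(
      hospitalization_id = excluded_ids,
      reason = rep("no_recorded_temperature", length(excluded_ids))
    )
  )
}

#' Summarize temperature-series exclusion accounting
#'
#' @param n_total Number of cohort encounters before exclusion.
#' @param n_excluded Number excluded for having no recorded temperatures.
#' @return A list with `n_total`, `n_excluded`, `n_analyzed`, `pct_excluded`
#'   (numeric, percent), and `pct_excluded_label` (formatted with the
#'   package's table rounding, e.g. `"0.07"`).
#' @export
exclusion_summary <- function(n_total, n_excluded) {
  stopifnot_scalar_number(n_total, "n_total")
  stopifnot_scalar_number(n_excluded, "n_excluded")
  pct <- 100 * n_excluded / n_total
  list(
    n_total = n_total,
    n_excluded = n_excluded,
    n_analyzed = n_total - n_excluded,
    pct_excluded = pct,
    pct_excluded_label = format_percent(pct)
  )
}

#' Assign subphenotypes by minimum mean squared error
#'
#' For each encounter, computes `mse_k = mean over observed hours of
#' (T_obs(h) - T_ref_k(h))^2` against each of the four reference curves and
#' assigns the label with the minimal MSE. Averaging over observed hours
#' (rather than summing) keeps the criterion scale-free across differing
#' observation counts, so sparse series are not penalized for missingness.
#' Ties break by the fixed label order NT < HT < HFR < HSR. Encounters need
#' at least `min_observations` observed hours (default 1 — only encounters
#' with no temperatures at all are excluded upstream).
#'
#' @param series Long series tibble from [build_temperature_series()]
#'   (columns `hospitalization_id`, `hour`, `temp_c`).
#' @param refset A `clif_reference_trajectories`; defaults to the package's
#'   synthetic stand-in curves ([default_reference_trajectories()]).
#' @param min_observations Minimum observed hours required (default 1).
#' @return A tibble of assignments: `hospitalization_id`, `n_observations`,
#'   `mse_NT`, `mse_HT`, `mse_HFR`, `mse_HSR`, and `subphenotype` (factor
#'   with levels NT, HT, HFR, HSR).
#' @export
classify_subphenotype <- function(series, refset = default_reference_trajectories(),
                                  min_observations = 1) {
  stopifnot(inherits(refset, "clif_reference_trajectories"))
  if (nrow(series) == 0) {
    rlang::abort("Empty temperature series; exclude zero-temperature encounters upstream.")
  }
  if (any(series$hour < 0 | series$hour > 72)) {
    rlang::abort("Series hours must lie in [0, 72].")
  }
  refmat <- as.matrix(as.data.frame(refset)[, SUBPHENOTYPE_LEVELS])
  hr <- as.integer(series$hour) + 1L
  sq_err <- (series$temp_c - refmat[hr, , drop = FALSE])^2
  colnames(sq_err) <- paste0("mse_", SUBPHENOTYPE_LEVELS)
  agg <- rowsum(cbind(sq_err, n_observations = 1), group = series$hospitalization_id)
  mse <- agg[, paste0("mse_", SUBPHENOTYPE_LEVELS), drop = FALSE] / agg[, "n_observations"]
  keep <- agg[, "n_observations"] >= min_observations
  # ties resolve to the earliest label in the fixed order
  assigned <- SUBPHENOTYPE_LEVELS[apply(mse, 1, which.min)]
  out <- tibble::tibble(
    hospitalization_id = rownames(agg),
    n_observations = as.integer(agg[, "n_observations"]),
    mse_NT = mse[, "mse_NT"], mse_HT = mse[, "mse_HT"],
    mse_HFR = mse[, "mse_HFR"], mse_HSR = mse[, "mse_HSR"],
    subphenotype = factor(assigned, levels = SUBPHENOTYPE_LEVELS)
  )
  out[keep, ]
}

#' Covariate-adjusted association of subphenotype with ICU outcomes
#'
#' Multivariable logistic regression of the outcome on subphenotype
#' indicators (normothermic reference) adjusted for patient age (continuous),
#' sex, race, and ethnicity (categorical), fitted by iteratively reweighted
#' least squares to convergence tolerance 1e-8. Perfect separation is
#' reported as a fit failure, never as silent output.
#'
#' @param assignments Assignment tibble from [classify_subphenotype()].
#' @param cohort Cohort tibble carrying `age_at_admission`, `sex_category`,
#'   `race_category`, `ethnicity_category`, `in_hospital_death`, `ever_imv`.
#' @param outcome `"mortality"` or `"imv"`.
#' @return An odds-ratio tibble: one row per subphenotype contrast (vs NT)
#'   with `coefficient`, `se`, `odds_ratio = exp(coefficient)`, and the Wald
#'   95% CI `exp(coefficient +/- 1.96 se)`; covariate rows are retained with
#'   `term_type = "covariate"` for forest-plot export.
#' @export
adjusted_outcome_model <- function(assignments, cohort, outcome = c("mortality", "imv")) {
  outcome <- match.arg(outcome)
  df <- assignments %>%
    dplyr::inner_join(cohort, by = "hospitalization_id") %>%
    dplyr::mutate(
      y = as.integer(if (outcome == "mortality") .data$in_hospital_death else .data$ever_imv),
      subphenotype = factor(.data$subphenotype, levels = SUBPHENOTYPE_LEVELS),
      sex = factor(.data$sex_category),
      race = factor(.data$race_category,
                    levels = c("white", "asian", "black", "other")),
      ethnicity = factor(.data$ethnicity_category,
                         levels = c("non_hispanic", "hispanic"))
    )
  if (length(unique(df$y)) < 2) {
    rlang::abort("Outcome has a single class; the adjusted model is not identifiable.")
  }
  if (sum(df$subphenotype == "NT", na.rm = TRUE) == 0) {
    rlang::abort("No normothermic encounters: the reference level is empty.")
  }
  df$subphenotype <- droplevels(df$subphenotype)
  df$sex <- droplevels(df$sex)
  df$race <- droplevels(df$race)
  df$ethnicity <- droplevels(df$ethnicity)
  terms <- c("subphenotype", "age_at_admission",
             if (nlevels(df$sex) > 1) "sex",
             if (nlevels(df$race) > 1) "race",
             if (nlevels(df$ethnicity) > 1) "ethnicity")
  rhs <- paste(terms, collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("y ~", rhs)), family = stats::binomial(),
                    data = df, control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    rlang::abort("Logistic model did not converge (possible separation); no estimates reported.")
  }
  cf <- summary(fit)$coefficients
  # separation on the estimands (the subphenotype contrasts) is a fit
  # failure; sparse covariate cells merely get wide intervals, as usual
  sub_rows <- grepl("^subphenotype", rownames(cf))
  if (any(abs(cf[sub_rows, "Estimate"]) > 20) || any(cf[sub_rows, "Std. Error"] > 50)) {
    rlang::abort("Diverging subphenotype estimates: separation detected, fit failure.")
  }
  est <- tibble::tibble(
    outcome = outcome,
    term = rownames(cf),
    coefficient = unname(cf[, "Estimate"]),
    se = unname(cf[, "Std. Error"])
  ) %>%
    dplyr::mutate(
      odds_ratio = exp(.data$coefficient),
      ci_low = exp(.data$coefficient - 1.96 * .data$se),
      ci_high = exp(.data$coefficient + 1.96 * .data$se),
      term_type = dplyr::if_else(grepl("^subphenotype", .data$term),
                                 "subphenotype_vs_NT", "covariate"),
      subphenotype = dplyr::if_else(.data$term_type == "subphenotype_vs_NT",
                                    sub("^subphenotype", "", .data$term), NA_character_)
    ) %>%
    dplyr::filter(.data$term != "(Intercept)")
  est
}
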