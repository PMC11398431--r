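#' Configuration for the synthetic CLIF generator
#'
#' Bundles every knob of the synthetic multi-site ICU encounter generator:
#' cohort size and seed, the study date window, demographic distributions
#' (Table-1-style age/sex/race/ethnicity mixes), ICU timing distributions,
#' outcome (mortality, invasive mechanical ventilation) logistic models,
#' temperature-subphenotype mixture weights and noise, measurement cadences,
#' outlier injection, and the fraction of encounters with no recorded
#' temperatures.
#'
#' Outcome models are specified by a target marginal prevalence plus log-odds
#' coefficients; the intercept is solved numerically at generation time so the
#' configured prevalence is the expected event rate.
#'
#' @param n_encounters Number of hospital encounters to simulate.
#' @param seed Integer seed; all randomness flows from it.
#' @param site Site label for the generated dataset.
#' @param date_window Character or Date length-2 vector: hospital admissions
#'   are drawn uniformly inside this window.
#' @param age_mean,age_sd Normal age distribution (years).
#' @param age_min Optional lower truncation for age (e.g. 18); `NULL` leaves
#'   the tail so cohort filters have work to do.
#' @param female_fraction Probability of `sex_category == "female"`.
#' @param race_probs,ethnicity_probs Named category probabilities.
#' @param icu_offset_mean_hours Mean of the exponential hospital-admission to
#'   ICU-entry offset (hours).
#' @param icu_los_meanlog,icu_los_sdlog Log-normal ICU length of stay (hours).
#' @param mortality,ventilation Lists with `target_prevalence` and log-odds
#'   coefficients (`age` per year, `albumin` per g/dL, named `subphenotype`
#'   vector over NT/HT/HFR/HSR).
#' @param subphenotype_weights Named mixture weights over NT/HT/HFR/HSR;
#'   must sum to 1.
#' @param temperature_noise_sd Gaussian noise SD around the reference curve
#'   (degrees C).
#' @param temperature_cadence_hours,vitals_cadence_hours Sampling cadence of
#'   the temperature stream and the other vital streams (hours).
#' @param lab_rate_per_day Poisson rate of repeat draws per lab analyte per
#'   ICU day (each analyte also gets one admission draw).
#' @param outlier_rate Fraction of vitals/labs rows replaced by implausible
#'   values (logged in the ground truth).
#' @param zero_temperature_fraction Fraction of encounters with no recorded
#'   temperatures at all.
#' @param icu_split_prob Probability that an encounter's ICU stay is recorded
#'   as two back-to-back ADT segments separated by a sub-hour gap (transfer
#'   artifact).
#' @param reference_trajectories Optional `clif_reference_trajectories` to
#'   generate temperatures from; defaults to
#'   [default_reference_trajectories()].
#' @return A list of class `clif_synth_config`.
#' @export
synth_config <- function(
    n_encounters = 500,
    seed = 1,
    site = "synthetic_site",
    date_window = c("2020-01-01", "2021-12-31"),
    age_mean = 60.6, age_sd = 17.2, age_min = NULL,
    female_fraction = 0.45,
    race_probs = c(asian = 0.036, black = 0.296, white = 0.587, other = 0.081),
    ethnicity_probs = c(hispanic = 0.07, non_hispanic = 0.93),
    icu_offset_mean_hours = 12,
    icu_los_meanlog = log(72), icu_los_sdlog = 0.8,
    mortality = list(
      target_prevalence = 0.095,
      age = 0.045, albumin = -1.6,
      subphenotype = c(NT = 0, HT = 0.6, HFR = 0.3, HSR = log(2))
    ),
    ventilation = list(
      target_prevalence = 0.38,
      age = 0, albumin = -0.2,
      subphenotype = c(NT = 0, HT = -0.1, HFR = 0.8, HSR = 1.5)
    ),
    subphenotype_weights = c(NT = 55.5, HT = 23.5, HFR = 7.05, HSR = 11.9) / 97.95,
    temperature_noise_sd = 0.3,
    temperature_cadence_hours = 1,
    vitals_cadence_hours = 2,
    lab_rate_per_day = 1.5,
    outlier_rate = 0,
    zero_temperature_fraction = 0.0007,
    icu_split_prob = 0.1,
    reference_trajectories = NULL) {
  cfg <- as.list(environment())
  if (n_encounters < 1) rlang::abort("`n_encounters` must be at least 1.")
  probs <- c(female_fraction, race_probs, ethnicity_probs,
             zero_temperature_fraction, outlier_rate, icu_split_prob,
             mortality$target_prevalence, ventilation$target_prevalence)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("All probabilities must lie in [0, 1].")
  }
  if (abs(sum(subphenotype_weights) - 1) > 1e-6 || any(subphenotype_weights < 0)) {
    rlang::abort("`subphenotype_weights` must be nonnegative and sum to 1.")
  }
  if (!setequal(names(subphenotype_weights), SUBPHENOTYPE_LEVELS)) {
    rlang::abort("`subphenotype_weights` must be named NT, HT, HFR, HSR.")
  }
  if (icu_offset_mean_hours <= 0 || icu_los_sdlog <= 0 ||
      temperature_noise_sd < 0 || lab_rate_per_day < 0) {
    rlang::abort("Infeasible config: duration/noise parameters must be positive.")
  }
  structure(cfg, class = "clif_synth_config")
}

# Solve the logistic intercept so that mean(plogis(b + lp)) hits the target.
solve_intercept <- function(lp, target) {
  stats::uniroot(function(b) mean(stats::plogis(b + lp)) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

outcome_linear_predictor <- function(model, age, age_mean, albumin, subph) {
  (model$age %||% 0) * (age - age_mean) +
    (model$albumin %||% 0) * (albumin - 3.2) +
    unname(model$subphenotype[subph])
}

#' Simulate encounter-level ground truth
#'
#' The encounter-level core of the generator: demographics, ICU timing,
#' subphenotype labels, latent labs, and outcomes drawn from the configured
#' logistic models. [generate_dataset()] expands this frame into full CLIF
#' tables; it is exported separately so large-sample statistical checks
#' (e.g. adjusted odds-ratio recovery) can run without building millions of
#' longitudinal rows.
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per encounter: identifiers, demographics,
#'   `admission_dttm`, `icu_entry_dttm`, `icu_exit_dttm`, `discharge_dttm`,
#'   timing in hours, subphenotype, latent albumin, true event probabilities
#'   (`p_death`, `p_imv`), outcomes (`death`, `imv`), `zero_temp`, and the
#'   cohort-qualification bookkeeping columns (`age_ok`, `offset_ok`,
#'   `los_ok`, `window_ok`, `qualifies`) evaluated at the consortium default
#'   criteria.
#' @export
generate_encounters <- function(config) {
  stopifnot(inherits(config, "clif_synth_config"))
  with_rng_seed(derive_seed(config$seed, "encounters"), {
    n <- config$n_encounters
    window <- as_utc(as.POSIXct(paste(config$date_window, c("00:00:00", "23:59:59")), tz = "UTC"))
    enc <- tibble::tibble(
      hospitalization_id = sprintf("H%06d", seq_len(n)),
      patient_id = sprintf("P%06d", seq_len(n)),
      hospital_id = sprintf("HOSP%02d", sample(1:3, n, replace = TRUE)),
      admission_dttm = window[1] + round(stats::runif(n, 0, as.numeric(difftime(window[2], window[1], units = "secs")))),
      age = round(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 0.2), 1),
      sex_category = sample(c("female", "male"), n, replace = TRUE,
                            prob = c(config$female_fraction, 1 - config$female_fraction)),
      race_category = sample(names(config$race_probs), n, replace = TRUE,
                             prob = config$race_probs),
      ethnicity_category = sample(names(config$ethnicity_probs), n, replace = TRUE,
                                  prob = config$ethnicity_probs),
      offset_h = stats::rexp(n, 1 / config$icu_offset_mean_hours),
      los_h = stats::rlnorm(n, config$icu_los_meanlog, config$icu_los_sdlog),
      subphenotype = sample(SUBPHENOTYPE_LEVELS, n, replace = TRUE,
                            prob = config$subphenotype_weights[SUBPHENOTYPE_LEVELS]),
      albumin_latent = pmin(pmax(stats::rnorm(n, 3.2, 0.6), 1), 5.5)
    )
    if (!is.null(config$age_min)) enc$age <- pmax(enc$age, config$age_min)

    lp_death <- outcome_linear_predictor(config$mortality, enc$age, config$age_mean,
                                         enc$albumin_latent, enc$subphenotype)
    b_death <- solve_intercept(lp_death, config$mortality$target_prevalence)
    enc$p_death <- stats::plogis(b_death + lp_death)
    enc$death <- stats::rbinom(n, 1, enc$p_death)

    lp_imv <- outcome_linear_predictor(config$ventilation, enc$age, config$age_mean,
                                       enc$albumin_latent, enc$subphenotype)
    b_imv <- solve_intercept(lp_imv, config$ventilation$target_prevalence)
    enc$p_imv <- stats::plogis(b_imv + lp_imv)
    enc$imv <- stats::rbinom(n, 1, enc$p_imv)

    enc$icu_entry_dttm <- enc$admission_dttm + round(hours(enc$offset_h))
    enc$icu_exit_dttm <- enc$icu_entry_dttm + round(hours(enc$los_h))
    post_h <- ifelse(enc$death == 1, 0, stats::rexp(n, 1 / 48))
    enc$discharge_dttm <- enc$icu_exit_dttm + round(hours(post_h))
    enc$discharge_category <- ifelse(
      enc$death == 1, "expired",
      sample(c("home", "snf", "rehab", "hospice", "ama", "other"), n, replace = TRUE,
             prob = c(0.6, 0.15, 0.1, 0.05, 0.05, 0.05))
    )
    enc$zero_temp <- stats::runif(n) < config$zero_temperature_fraction

    # Cohort-qualification bookkeeping under the consortium default criteria,
    # computed from the latent quantities (the oracle for cohort discovery).
    enc$age_ok <- enc$age >= 18
    enc$offset_ok <- enc$offset_h <= 48
    enc$los_ok <- enc$los_h >= 24
    enc$window_ok <- as.Date(enc$admission_dttm) >= as.Date(config$date_window[1]) &
      as.Date(enc$admission_dttm) <= as.Date(config$date_window[2])
    enc$qualifies <- enc$age_ok & enc$offset_ok & enc$los_ok & enc$window_ok
    enc
  })
}

# Expand per-encounter hourly grids: indices into `enc` and hour offsets.
expand_grid_hours <- function(max_hour, by) {
  seqs <- lapply(max_hour, function(m) seq(0, max(m, 0), by = by))
  list(idx = rep(seq_along(max_hour), lengths(seqs)),
       hour = unlist(seqs, use.names = FALSE))
}

#' Generate a CLIF-conformant synthetic dataset with ground truth
#'
#' Expands [generate_encounters()] into the full set of CLIF tables (patient,
#' hospitalization, adt, vitals, labs, respiratory_support,
#' medication_admin_continuous, scores). Temperature streams follow each
#' encounter's true subphenotype reference curve plus i.i.d. Gaussian noise at
#' the configured cadence; labs are drawn at Poisson-thinned times around
#' per-encounter latent values; outcomes come from the configured logistic
#' models so adjusted odds-ratio recovery is well-posed. If `outlier_rate > 0`
#' a matching fraction of vitals/labs values is replaced by values outside the
#' consortium default plausibility ranges and logged row-by-row in the ground
#' truth, making outlier cleaning exactly testable.
#'
#' Identical configs (same seed) yield identical datasets.
#'
#' @param config A [synth_config()].
#' @param registry Schema registry used for the dataset container.
#' @return A list with elements `dataset` (a [clif_dataset] that passes
#'   [validate_dataset()]), `ground_truth` (list of `encounters` and
#'   `outliers` tibbles), and `config`.
#' @export
generate_dataset <- function(config, registry = clif_schema_registry()) {
  stopifnot(inherits(config, "clif_synth_config"))
  enc <- generate_encounters(config)
  refs <- config$reference_trajectories %||% default_reference_trajectories()
  refmat <- as.matrix(as.data.frame(refs)[, SUBPHENOTYPE_LEVELS])

  tabs <- with_rng_seed(derive_seed(config$seed, "tables"), {
    n <- nrow(enc)

    patient <- tibble::tibble(
      patient_id = enc$patient_id,
      race_name = toupper(enc$race_category),
      race_category = enc$race_category,
      ethnicity_name = toupper(enc$ethnicity_category),
      ethnicity_category = enc$ethnicity_category,
      sex_name = toupper(enc$sex_category),
      sex_category = enc$sex_category,
      birth_date = enc$admission_dttm - round(enc$age * 365.25 * 86400),
      death_dttm = as.POSIXct(ifelse(enc$death == 1, enc$discharge_dttm, NA),
                              tz = "UTC", origin = "1970-01-01")
    )

    hospitalization <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id,
      patient_id = enc$patient_id,
      admission_dttm = enc$admission_dttm,
      discharge_dttm = enc$discharge_dttm,
      age_at_admission = enc$age,
      discharge_name = toupper(enc$discharge_category),
      discharge_category = enc$discharge_category
    )

    # --- ADT: pre-ICU segment, ICU segment(s), optional post-ICU ward ---
    pre <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id,
      hospital_id = enc$hospital_id,
      in_dttm = enc$admission_dttm,
      out_dttm = enc$icu_entry_dttm,
      location_category = ifelse(enc$offset_h <= 8, "ed", "ward")
    )
    split <- stats::runif(n) < config$icu_split_prob & enc$los_h > 4
    cut_h <- stats::runif(n, 0.3, 0.6) * enc$los_h
    gap_h <- stats::runif(n, 0.05, 0.9)
    icu1 <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id,
      hospital_id = enc$hospital_id,
      in_dttm = enc$icu_entry_dttm,
      out_dttm = as.POSIXct(ifelse(split, enc$icu_entry_dttm + round(hours(cut_h)),
                                   enc$icu_exit_dttm),
                            tz = "UTC", origin = "1970-01-01"),
      location_category = "icu"
    )
    icu2 <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[split],
      hospital_id = enc$hospital_id[split],
      in_dttm = enc$icu_entry_dttm[split] + round(hours(cut_h[split] + gap_h[split])),
      out_dttm = enc$icu_exit_dttm[split],
      location_category = "icu"
    )
    post_idx <- which(enc$discharge_dttm > enc$icu_exit_dttm)
    post <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[post_idx],
      hospital_id = enc$hospital_id[post_idx],
      in_dttm = enc$icu_exit_dttm[post_idx],
      out_dttm = enc$discharge_dttm[post_idx],
      location_category = "ward"
    )
    adt <- dplyr::bind_rows(pre, icu1, icu2, post)
    adt$location_name <- toupper(adt$location_category)
    adt <- dplyr::arrange(adt, .data$hospitalization_id, .data$in_dttm)

    # --- vitals: temperature at its own cadence, other streams coarser ---
    max_temp_h <- pmin(72, floor(enc$los_h))
    temp_take <- which(!enc$zero_temp)
    gt_temp <- expand_grid_hours(max_temp_h[temp_take], config$temperature_cadence_hours)
    t_idx <- temp_take[gt_temp$idx]
    temp_vals <- refmat[cbind(gt_temp$hour + 1L,
                              match(enc$subphenotype[t_idx], SUBPHENOTYPE_LEVELS))] +
      stats::rnorm(length(t_idx), 0, config$temperature_noise_sd)
    temperature <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[t_idx],
      recorded_dttm = enc$icu_entry_dttm[t_idx] + hours(gt_temp$hour),
      vital_name = "TEMPERATURE CORE",
      vital_category = "temp_c",
      vital_value = round(temp_vals, 2)
    )

    vital_streams <- list(
      heart_rate = c(mean = 88, sd = 14), sbp = c(mean = 118, sd = 16),
      dbp = c(mean = 64, sd = 11), spo2 = c(mean = 96.3, sd = 1.8),
      respiratory_rate = c(mean = 20, sd = 4)
    )
    gv <- expand_grid_hours(pmin(72, floor(enc$los_h)), config$vitals_cadence_hours)
    other_vitals <- dplyr::bind_rows(lapply(names(vital_streams), function(cat) {
      p <- vital_streams[[cat]]
      vals <- stats::rnorm(length(gv$idx), p[["mean"]], p[["sd"]])
      if (cat == "spo2") vals <- pmin(vals, 100)
      tibble::tibble(
        hospitalization_id = enc$hospitalization_id[gv$idx],
        recorded_dttm = enc$icu_entry_dttm[gv$idx] + hours(gv$hour),
        vital_name = toupper(gsub("_", " ", cat)),
        vital_category = cat,
        vital_value = round(vals, 1)
      )
    }))
    vitals <- dplyr::bind_rows(temperature, other_vitals)
    vitals <- dplyr::arrange(vitals, .data$hospitalization_id, .data$recorded_dttm,
                             .data$vital_category)

    # --- labs: one admission panel plus Poisson-thinned repeats ---
    lab_centers <- function(analyte, k, idx) {
      switch(analyte,
        albumin = stats::rnorm(k, enc$albumin_latent[idx], 0.25),
        ast = stats::rlnorm(k, log(42), 0.6),
        hemoglobin = stats::rnorm(k, 11.6, 2),
        creatinine = stats::rlnorm(k, log(1.1), 0.5),
        lactate = stats::rlnorm(k, log(1.8), 0.5),
        wbc = stats::rlnorm(k, log(10), 0.4),
        sodium = stats::rnorm(k, 140, 4),
        potassium = stats::rnorm(k, 4.1, 0.5)
      )
    }
    analytes <- c("albumin", "ast", "hemoglobin", "creatinine",
                  "lactate", "wbc", "sodium", "potassium")
    labs <- dplyr::bind_rows(lapply(analytes, function(a) {
      n_extra <- stats::rpois(n, config$lab_rate_per_day * enc$los_h / 24)
      counts <- n_extra + 1L # admission panel draw + repeats
      idx <- rep(seq_len(n), counts)
      first <- !duplicated(idx)
      at_h <- stats::runif(length(idx), 0, pmin(enc$los_h[idx], 24 * 7))
      at_h[first] <- stats::runif(sum(first), 0.5, 2)
      tibble::tibble(
        hospitalization_id = enc$hospitalization_id[idx],
        lab_result_dttm = enc$icu_entry_dttm[idx] + round(hours(at_h)),
        lab_name = paste0("SITE_LAB ", toupper(a), " - AUTOMATED"),
        lab_category = a,
        lab_value_numeric = round(lab_centers(a, length(idx), idx), 2)
      )
    }))
    labs$lab_order_dttm <- labs$lab_result_dttm - 3600
    labs <- dplyr::arrange(labs, .data$hospitalization_id, .data$lab_result_dttm,
                           .data$lab_category)

    # --- respiratory support: IMV encounters get ventilator rows ---
    imv_idx <- which(enc$imv == 1)
    vent_start_h <- stats::runif(length(imv_idx), 0, pmin(12, enc$los_h[imv_idx] / 2))
    vent_dur_h <- pmin(stats::rlnorm(length(imv_idx), log(48), 0.6),
                       enc$los_h[imv_idx] - vent_start_h)
    gvent <- expand_grid_hours(pmax(vent_dur_h, 0), 4)
    resp_imv <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[imv_idx][gvent$idx],
      recorded_dttm = enc$icu_entry_dttm[imv_idx][gvent$idx] +
        round(hours(vent_start_h[gvent$idx] + gvent$hour)),
      device_name = "VENTILATOR",
      device_category = "imv",
      mode_name = "AC/VC",
      mode_category = "assist_control_volume",
      fio2_set = round(stats::runif(length(gvent$idx), 0.3, 1), 2),
      peep_set = sample(c(5, 8, 10, 12, 15), length(gvent$idx), replace = TRUE)
    )
    noimv_idx <- which(enc$imv == 0)
    resp_nc <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[noimv_idx],
      recorded_dttm = enc$icu_entry_dttm[noimv_idx] + hours(1),
      device_name = "NASAL CANNULA",
      device_category = "nasal_cannula",
      mode_name = NA_character_,
      mode_category = NA_character_,
      fio2_set = NA_real_,
      peep_set = NA_real_
    )
    respiratory_support <- dplyr::arrange(dplyr::bind_rows(resp_imv, resp_nc),
                                          .data$hospitalization_id, .data$recorded_dttm)

    # --- continuous meds: norepinephrine for a sicker subset ---
    pressor <- which(stats::runif(n) < stats::plogis(-2 + 2 * enc$death))
    gmed <- expand_grid_hours(pmin(48, floor(enc$los_h[pressor])), 4)
    medication_admin_continuous <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[pressor][gmed$idx],
      admin_dttm = enc$icu_entry_dttm[pressor][gmed$idx] + hours(gmed$hour),
      med_name = "NOREPINEPHRINE 8MG/250ML",
      med_category = "norepinephrine",
      med_dose = round(stats::rlnorm(length(gmed$idx), log(8), 0.5), 1),
      med_dose_unit = "mcg/min"
    )

    # --- scores: daily GCS ---
    gsc <- expand_grid_hours(pmin(72, floor(enc$los_h)), 24)
    scores <- tibble::tibble(
      hospitalization_id = enc$hospitalization_id[gsc$idx],
      recorded_dttm = enc$icu_entry_dttm[gsc$idx] + hours(gsc$hour),
      score_name = "GLASGOW COMA SCALE TOTAL",
      score_category = "gcs_total",
      score_value = sample(3:15, length(gsc$idx), replace = TRUE,
                           prob = c(rep(1, 6), rep(2, 4), rep(6, 3)))
    )

    list(
      patient = patient, hospitalization = hospitalization, adt = adt,
      vitals = vitals, labs = labs, respiratory_support = respiratory_support,
      medication_admin_continuous = medication_admin_continuous, scores = scores
    )
  })

  # Clip physiologic values into the consortium default plausibility ranges
  # so that injected outliers are the only out-of-range values.
  ranges <- default_outlier_ranges()
  tabs$vitals <- clip_to_ranges(tabs$vitals, ranges, "vitals",
                                "vital_category", "vital_value")
  tabs$labs <- clip_to_ranges(tabs$labs, ranges, "labs",
                              "lab_category", "lab_value_numeric")

  outliers <- tibble::tibble(
    table = character(0), hospitalization_id = character(0),
    recorded_dttm = as.POSIXct(character(0), tz = "UTC"),
    category = character(0), injected_value = numeric(0)
  )
  if (config$outlier_rate > 0) {
    inject <- with_rng_seed(derive_seed(config$seed, "outliers"), {
      lapply(list(
        list(tab = "vitals", cat = "vital_category", val = "vital_value",
             tcol = "recorded_dttm"),
        list(tab = "labs", cat = "lab_category", val = "lab_value_numeric",
             tcol = "lab_result_dttm")
      ), function(loc) {
        df <- tabs[[loc$tab]]
        k <- stats::rbinom(1, nrow(df), config$outlier_rate)
        rows <- sort(sample(nrow(df), k))
        lut <- stats::setNames(ranges$max_plausible,
                               paste(ranges$stream, ranges$category))
        hi <- lut[paste(loc$tab, df[[loc$cat]][rows])]
        inj <- round(hi * 3 + 100, 1) # e.g. heart rate 20-300 -> injected 1000
        df[[loc$val]][rows] <- inj
        tabs[[loc$tab]] <<- df
        tibble::tibble(
          table = loc$tab,
          hospitalization_id = df$hospitalization_id[rows],
          recorded_dttm = df[[loc$tcol]][rows],
          category = df[[loc$cat]][rows],
          injected_value = inj
        )
      })
    })
    outliers <- dplyr::bind_rows(inject)
  }

  gt <- list(
    encounters = dplyr::mutate(
      enc,
      n_temp_hours = ifelse(enc$zero_temp, 0L,
                            floor(pmin(72, floor(enc$los_h)) /
                                    config$temperature_cadence_hours) + 1L)
    ),
    outliers = outliers
  )
  list(
    dataset = clif_dataset(tabs, site = config$site, registry = registry),
    ground_truth = gt,
    config = config
  )
}

clip_to_ranges <- function(df, ranges, stream, cat_col, val_col) {
  r <- ranges[ranges$stream == stream, ]
  m <- match(df[[cat_col]], r$category)
  lo <- r$min_plausible[m]
  hi <- r$max_plausible[m]
  ok <- !is.na(m)
  df[[val_col]][ok] <- pmin(pmax(df[[val_col]][ok], lo[ok]), hi[ok])
  df
}
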