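#' Feature specification for the first-24-hour window
#'
#' A feature spec lists (stream, category, aggregation, output name) tuples;
#' each is aggregated over a half-open window `[icu_entry, icu_entry + 24 h)`
#' so a later window never double-counts the boundary observation.
#' Aggregations are restricted to `min`, `max`, and `mean`.
#'
#' @param features A data frame with columns `stream` (`"vitals"` or
#'   `"labs"`), `category`, `stat` (`min`/`max`/`mean`), and `name` (unique
#'   output column name).
#' @param window_hours Length-2 numeric window in hours from ICU entry
#'   (default `c(0, 24)`).
#' @return A list of class `clif_feature_spec`.
#' @export
feature_spec <- function(features, window_hours = c(0, 24)) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("stream", "category", "stat", "name") %in% names(features)))
  if (!all(features$stat %in% c("min", "max", "mean"))) {
    rlang::abort("Aggregations are restricted to min, max, mean.")
  }
  if (!all(features$stream %in% c("vitals", "labs"))) {
    rlang::abort("Feature streams must be 'vitals' or 'labs'.")
  }
  if (anyDuplicated(features$name)) {
    rlang::abort("Feature output names must be unique.")
  }
  structure(list(features = features, window_hours = window_hours),
            class = "clif_feature_spec")
}

#' Default mortality-model feature specification
#'
#' The five headline predictors of the bundled mortality model (minimum
#' albumin, maximum and mean AST, minimum pulse rate, minimum diastolic blood
#' pressure) plus a documented placeholder list of common first-24-hour
#' vitals/labs aggregates. The full 30-predictor production list is
#' site-configurable: pass any [feature_spec()] to the extraction and
#' training functions.
#'
#' @return A `clif_feature_spec`.
#' @export
default_feature_spec <- function() {
  f <- tibble::tribble(
    ~stream, ~category, ~stat, ~name,
    "labs",   "albumin",          "min",  "min_albumin",
    "labs",   "ast",              "max",  "max_ast",
    "labs",   "ast",              "mean", "mean_ast",
    "vitals", "heart_rate",       "min",  "min_pulse",
    "vitals", "dbp",              "min",  "min_dbp",
    "vitals", "sbp",              "min",  "min_sbp",
    "vitals", "heart_rate",       "max",  "max_pulse",
    "vitals", "spo2",             "min",  "min_spo2",
    "vitals", "respiratory_rate", "max",  "max_respiratory_rate",
    "vitals", "temp_c",           "max",  "max_temp_c",
    "labs",   "creatinine",       "max",  "max_creatinine",
    "labs",   "hemoglobin",       "min",  "min_hemoglobin",
    "labs",   "lactate",          "max",  "max_lactate",
    "labs",   "wbc",              "max",  "max_wbc",
    "labs",   "sodium",           "min",  "min_sodium"
  )
  feature_spec(f)
}

stream_observations <- function(dataset, stream) {
  if (!stream %in% names(dataset$tables)) {
    return(tibble::tibble(hospitalization_id = character(0),
                          obs_dttm = as.POSIXct(character(0), tz = "UTC"),
                          category = character(0), value = numeric(0)))
  }
  tab <- dataset$tables[[stream]]
  if (stream == "vitals") {
    tibble::tibble(hospitalization_id = tab$hospitalization_id,
                   obs_dttm = tab$recorded_dttm,
                   category = norm_category(tab$vital_category),
                   value = tab$vital_value)
  } else {
    tibble::tibble(hospitalization_id = tab$hospitalization_id,
                   obs_dttm = tab$lab_result_dttm,
                   category = norm_category(tab$lab_category),
                   value = tab$lab_value_numeric)
  }
}

#' Extract first-24-hour feature aggregates for a cohort
#'
#' Aggregates each spec entry over observations with a timestamp in
#' `[icu_entry + w0, icu_entry + w1)` hours. Encounters with zero
#' observations for a feature get a missing value — never an imputation; the
#' downstream gradient-boosting backend handles missingness natively.
#' Run outlier cleaning ([apply_outlier_ranges()]) first.
#'
#' @param dataset A cleaned [clif_dataset].
#' @param cohort Cohort tibble from [discover_icu_cohort()].
#' @param spec A [feature_spec()]; defaults to [default_feature_spec()].
#' @return A tibble (`clif_feature_matrix`) with one row per cohort
#'   encounter: `hospitalization_id`, one column per feature, and the label
#'   column `in_hospital_death` (0/1).
#' @export
extract_features <- function(dataset, cohort, spec = default_feature_spec()) {
  stopifnot(inherits(dataset, "clif_dataset"), inherits(spec, "clif_feature_spec"))
  vocabs <- clif_vocabularies()
  known <- c(vocabs$vital_category$permitted, vocabs$lab_category$permitted)
  unknown <- setdiff(norm_category(spec$features$category), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Feature spec references unknown categor%s: %s",
                         if (length(unknown) > 1) "ies" else "y",
                         paste(unknown, collapse = ", ")))
  }
  w <- spec$window_hours
  out <- cohort[, "hospitalization_id", drop = FALSE]
  for (stream in unique(spec$features$stream)) {
    obs <- stream_observations(dataset, stream) %>%
      dplyr::inner_join(cohort[, c("hospitalization_id", "icu_entry_dttm")],
                        by = "hospitalization_id") %>%
      dplyr::mutate(h = as.numeric(difftime(.data$obs_dttm, .data$icu_entry_dttm,
                                            units = "hours"))) %>%
      dplyr::filter(.data$h >= w[1], .data$h < w[2], !is.na(.data$value))
    fs <- spec$features[spec$features$stream == stream, ]
    for (i in seq_len(nrow(fs))) {
      sub <- obs[obs$category == norm_category(fs$category[i]), ]
      if (nrow(sub) == 0) {
        out[[fs$name[i]]] <- NA_real_
        next
      }
      agg <- sub %>%
        dplyr::group_by(.data$hospitalization_id) %>%
        dplyr::summarise(v = switch(fs$stat[i],
                                    min = min(.data$value),
                                    max = max(.data$value),
                                    mean = mean(.data$value)),
                         .groups = "drop")
      names(agg)[2] <- fs$name[i]
      out <- dplyr::left_join(out, agg, by = "hospitalization_id")
    }
  }
  out$in_hospital_death <- as.integer(cohort$in_hospital_death[
    match(out$hospitalization_id, cohort$hospitalization_id)
  ])
  class(out) <- c("clif_feature_matrix", class(out))
  out
}

feature_matrix_to_xgb <- function(features, feature_names) {
  m <- as.matrix(as.data.frame(features)[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Default hyperparameter grid for the mortality model
#'
#' Conservative settings (shallow trees, small learning rates, a minimum
#' child weight of 5) suited to clinical cohorts where events are scarce
#' relative to features; aggressive grids overfit badly at typical
#' in-hospital mortality prevalences.
#'
#' @return A data frame of grid points (`eta`, `max_depth`, `nrounds`).
#' @export
default_hyperparameter_grid <- function() {
  expand.grid(eta = c(0.05, 0.1), max_depth = c(2L, 3L), nrounds = 120L,
              KEEP.OUT.ATTRS = FALSE)
}

#' Train the in-hospital mortality model
#'
#' Grid search with k-fold cross-validation over a gradient-boosted binary
#' classifier (the package's backend is xgboost, chosen for native
#' missing-value handling so cases never need imputation or exclusion). The
#' grid point with the best mean cross-validated AUC wins and the final model
#' is refit on all rows. Deterministic for a fixed `seed`.
#'
#' @param features A `clif_feature_matrix` from [extract_features()].
#' @param grid Hyperparameter grid (data frame with `eta`, `max_depth`,
#'   `nrounds`); defaults to [default_hyperparameter_grid()].
#' @param k_folds Number of cross-validation folds (default 5).
#' @param seed Seed for fold assignment and the booster.
#' @return A `clif_mortality_model`: the fitted booster, feature names,
#'   chosen hyperparameters, the CV table, and the training prevalence.
#' @export
train_mortality_model <- function(features, grid = default_hyperparameter_grid(),
                                  k_folds = 5, seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  label <- features$in_hospital_death
  if (length(unique(label)) < 2) {
    rlang::abort("Training labels are single-class; cannot fit a classifier.")
  }
  feature_names <- setdiff(names(features), c("hospitalization_id", "in_hospital_death"))
  x <- feature_matrix_to_xgb(features, feature_names)

  folds <- with_rng_seed(derive_seed(seed, "cv_folds"), {
    sample(rep_len(seq_len(k_folds), nrow(x)))
  })
  cv <- grid
  cv$mean_cv_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(k_folds), function(k) {
      tr <- folds != k
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = grid$eta[g],
                      max_depth = grid$max_depth[g], min_child_weight = 5,
                      nthread = 1, seed = derive_seed(seed, "booster")),
        data = xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = label[tr]),
        nrounds = grid$nrounds[g], verbose = 0
      )
      pred <- stats::predict(booster, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      if (length(unique(label[!tr])) < 2) return(NA_real_)
      auc(pred, label[!tr])
    }, numeric(1))
    cv$mean_cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv$mean_cv_auc)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = grid$eta[best],
                  max_depth = grid$max_depth[best], min_child_weight = 5,
                  nthread = 1, seed = derive_seed(seed, "booster")),
    data = xgboost::xgb.DMatrix(x, label = label),
    nrounds = grid$nrounds[best], verbose = 0
  )
  structure(
    list(
      booster = booster,
      feature_names = feature_names,
      best_params = as.list(cv[best, setdiff(names(cv), "mean_cv_auc")]),
      cv_results = tibble::as_tibble(cv),
      train_prevalence = mean(label)
    ),
    class = "clif_mortality_model"
  )
}

#' @export
print.clif_mortality_model <- function(x, ...) {
  cat(sprintf(
    "<clif_mortality_model> %d features; best grid point eta=%g, max_depth=%d, nrounds=%d (CV AUC %.3f)\n",
    length(x$feature_names), x$best_params$eta, x$best_params$max_depth,
    x$best_params$nrounds, max(x$cv_results$mean_cv_auc)
  ))
  invisible(x)
}

#' Predict in-hospital death risk
#'
#' @param model A `clif_mortality_model` (or one loaded with
#'   [load_mortality_model()]).
#' @param features A feature matrix whose columns match the training spec;
#'   a mismatch is an error. All-missing rows still yield a valid
#'   probability.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "clif_mortality_model"))
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Feature matrix is missing model column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  x <- feature_matrix_to_xgb(features, model$feature_names)
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(x))
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' Save / load the mortality model in a portable text format
#'
#' The booster is exported as backend-native JSON text (the portable
#' interchange format for cross-site reuse) together with a `.meta.json`
#' sidecar holding feature names, hyperparameters, and training prevalence.
#'
#' @param model A `clif_mortality_model`.
#' @param path Output path for the booster JSON (e.g. `"model.json"`); the
#'   sidecar is written next to it.
#' @return `path` invisibly; `load_mortality_model` returns the model.
#' @export
save_mortality_model <- function(model, path) {
  stopifnot(inherits(model, "clif_mortality_model"), grepl("\\.json$", path))
  xgboost::xgb.save(model$booster, path)
  meta <- list(
    feature_names = model$feature_names,
    best_params = model$best_params,
    train_prevalence = model$train_prevalence
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mortality_model
#' @export
load_mortality_model <- function(path) {
  booster <- xgboost::xgb.load(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(
    list(booster = booster, feature_names = meta$feature_names,
         best_params = meta$best_params, cv_results = NULL,
         train_prevalence = meta$train_prevalence),
    class = "clif_mortality_model"
  )
}
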