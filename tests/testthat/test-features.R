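test_that("aggregates respect the half-open 24-hour window", {
  ds <- handmade_dataset()
  entry <- utc("2020-06-03 00:00")
  ds$tables$labs <- tibble::tibble(
    hospitalization_id = "H1",
    lab_order_dttm = entry,
    lab_result_dttm = entry + c(3, 20, 25, 24) * 3600,
    lab_name = c("ALB", "ALB", "AST", "AST"),
    lab_category = c("albumin", "albumin", "ast", "ast"),
    lab_value_numeric = c(2.1, 3.0, 180, 99),
    reference_unit = ""
  )
  spec <- feature_spec(tibble::tibble(
    stream = c("labs", "labs"), category = c("albumin", "ast"),
    stat = c("min", "max"), name = c("min_albumin", "max_ast")
  ))
  fm <- extract_features(ds, make_cohort_row(), spec)
  expect_identical(fm$min_albumin, 2.1)
  # AST only at hours 24 and 25: outside [0, 24) -> missing
  expect_true(is.na(fm$max_ast))
})

test_that("extraction matches a brute-force oracle exactly on synthetic data", {
  res <- test_synth()
  cleaned <- apply_outlier_ranges(res$dataset)
  cohort <- discover_icu_cohort(cleaned$dataset)
  cohort <- cohort[seq_len(min(200, nrow(cohort))), ]
  spec <- default_feature_spec()
  fast <- extract_features(cleaned$dataset, cohort, spec)
  slow <- extract_features_oracle(cleaned$dataset, cohort, spec)
  for (nm in spec$features$name) {
    expect_equal(fast[[nm]], slow[[nm]], tolerance = 0, info = nm)
  }
})

test_that("extraction ignores row order and late poisoned observations", {
  res <- test_synth()
  cohort <- discover_icu_cohort(res$dataset)[1:50, ]
  base <- extract_features(res$dataset, cohort)

  shuffled <- res$dataset
  set.seed(1)
  shuffled$tables$vitals <- shuffled$tables$vitals[sample(nrow(shuffled$tables$vitals)), ]
  shuffled$tables$labs <- shuffled$tables$labs[sample(nrow(shuffled$tables$labs)), ]
  expect_equal(extract_features(shuffled, cohort), base, tolerance = 0)

  poisoned <- res$dataset
  poisoned$tables$labs <- tibble::add_row(
    poisoned$tables$labs,
    hospitalization_id = cohort$hospitalization_id[1],
    lab_order_dttm = cohort$icu_entry_dttm[1] + 30 * 3600,
    lab_result_dttm = cohort$icu_entry_dttm[1] + 30 * 3600, # hour 30: outside window
    lab_name = "POISON", lab_category = "albumin", lab_value_numeric = 0.6
  )
  expect_equal(extract_features(poisoned, cohort), base, tolerance = 0)
})

test_that("a spec referencing an unknown category is a configuration error", {
  expect_error(
    extract_features(test_synth()$dataset, make_cohort_row(),
                     feature_spec(tibble::tibble(
                       stream = "labs", category = "midichlorians",
                       stat = "min", name = "x"
                     ))),
    "unknown categor"
  )
  expect_error(feature_spec(tibble::tibble(stream = "labs", category = "albumin",
                                           stat = "median", name = "x")),
               "min, max, mean")
  expect_error(feature_spec(tibble::tibble(stream = c("labs", "labs"),
                                           category = c("albumin", "ast"),
                                           stat = "min", name = c("x", "x"))),
               "unique")
})

test_that("training finds real signal, finds none in shuffled labels, and is deterministic", {
  cfg <- synth_config(n_encounters = 2000, seed = 31)
  res <- generate_dataset(cfg)
  cleaned <- apply_outlier_ranges(res$dataset)
  cohort <- discover_icu_cohort(cleaned$dataset)
  fm <- extract_features(cleaned$dataset, cohort)

  half <- seq_len(nrow(fm)) %% 2 == 0
  model <- train_mortality_model(fm[half, ], seed = 7)
  scores <- predict_risk(model, fm[!half, ])
  labels <- fm$in_hospital_death[!half]

  # permutation null for the test-set AUC standard error
  set.seed(99)
  null_aucs <- replicate(200, auc(scores, sample(labels)))
  expect_gt(auc(scores, labels), 0.5 + 3 * stats::sd(null_aucs))

  # shuffled labels: cross-validated AUC consistent with chance
  fm_null <- fm[half, ]
  set.seed(5)
  fm_null$in_hospital_death <- sample(fm_null$in_hospital_death)
  null_model <- train_mortality_model(fm_null, seed = 7)
  best_cv <- max(null_model$cv_results$mean_cv_auc)
  expect_lt(abs(best_cv - 0.5), 3 * stats::sd(null_aucs) + 0.05)

  # determinism: identical chosen hyperparameters and predictions
  model2 <- train_mortality_model(fm[half, ], seed = 7)
  expect_identical(model2$best_params, model$best_params)
  expect_identical(predict_risk(model2, fm[!half, ]), scores)
})

test_that("prediction tolerates missingness and round-trips through the text format", {
  res <- test_synth()
  cleaned <- apply_outlier_ranges(res$dataset)
  cohort <- discover_icu_cohort(cleaned$dataset)
  fm <- extract_features(cleaned$dataset, cohort)
  model <- train_mortality_model(fm, grid = data.frame(eta = 0.3, max_depth = 3L, nrounds = 30L),
                                 seed = 2)

  all_missing <- fm[1, ]
  all_missing[model$feature_names] <- NA_real_
  p <- predict_risk(model, all_missing)
  expect_true(is.finite(p) && p >= 0 && p <= 1)

  # calibration in the large on in-distribution data
  expect_lt(abs(mean(predict_risk(model, fm)) - mean(fm$in_hospital_death)), 0.05)

  # schema mismatch is an error
  expect_error(predict_risk(model, fm[, 1:3]), "missing model column")

  # portable text serialization preserves predictions
  dir <- withr::local_tempdir()
  save_mortality_model(model, file.path(dir, "model.json"))
  expect_true(file.exists(file.path(dir, "model.json.meta.json")))
  loaded <- load_mortality_model(file.path(dir, "model.json"))
  expect_equal(predict_risk(loaded, fm), predict_risk(model, fm), tolerance = 1e-7)
  expect_identical(loaded$feature_names, model$feature_names)

  # single-class labels cannot train
  fm1 <- fm
  fm1$in_hospital_death <- 0L
  expect_error(train_mortality_model(fm1), "single-class")
})
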