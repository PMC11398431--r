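ref_series <- function(label, id = "X", hours = 0:72,
                       refs = default_reference_trajectories()) {
  tibble::tibble(hospitalization_id = id, hour = hours,
                 temp_c = refs[[label]][hours + 1])
}

test_that("temperature series are hour-binned means with Fahrenheit conversion", {
  ds <- handmade_dataset()
  entry <- utc("2020-06-03 00:00")
  ds$tables$vitals <- tibble::tibble(
    hospitalization_id = "H1",
    recorded_dttm = entry + c(5.2, 5.8, 10) * 3600,
    vital_name = "TEMP",
    vital_category = c("temp_c", "temp_c", "temp_f"),
    vital_value = c(36.8, 37.2, 98.6)
  )
  out <- build_temperature_series(ds, make_cohort_row())
  s <- out$series
  expect_identical(s$temp_c[s$hour == 5], 37.0)          # within-hour mean
  expect_equal(s$temp_c[s$hour == 10], 37.0)             # (98.6 - 32) * 5/9
  expect_identical(nrow(out$exclusions), 0L)
})

test_that("zero-temperature encounters are excluded, matching ground truth exactly", {
  res <- test_synth()
  gt <- res$ground_truth$encounters
  cohort <- discover_icu_cohort(res$dataset)
  out <- build_temperature_series(res$dataset, cohort)
  truth <- gt$hospitalization_id[gt$zero_temp & gt$qualifies]
  expect_setequal(out$exclusions$hospitalization_id, truth)
  expect_true(all(out$exclusions$reason == "no_recorded_temperature"))
  # exclusion accounting helper
  acc <- exclusion_summary(nrow(cohort), nrow(out$exclusions))
  expect_identical(acc$n_analyzed, nrow(cohort) - nrow(out$exclusions))
})

test_that("classification is exact on reference curves and breaks ties by label order", {
  refs <- default_reference_trajectories()
  a <- classify_subphenotype(ref_series("NT"), refs)
  expect_identical(as.character(a$subphenotype), "NT")
  expect_identical(a$mse_NT, 0)
  expect_identical(a$n_observations, 73L)

  # exact tie: constant curves symmetric around the observed series -> NT wins
  flat <- reference_trajectories(tibble::tibble(
    hour = 0:72, NT = 36.5, HT = 37.5, HFR = 39, HSR = 40
  ))
  mid <- tibble::tibble(hospitalization_id = "M", hour = 0:72, temp_c = 37)
  tie <- classify_subphenotype(mid, flat)
  expect_identical(tie$mse_NT, tie$mse_HT)
  expect_identical(as.character(tie$subphenotype), "NT")

  expect_error(classify_subphenotype(ref_series("NT")[0, ], refs), "Empty")
  expect_error(classify_subphenotype(tibble::tibble(
    hospitalization_id = "B", hour = 80, temp_c = 37)), "\\[0, 72\\]")
})

test_that("classification agrees with the naive oracle on random sparse series", {
  refs <- default_reference_trajectories()
  set.seed(7)
  series <- dplyr::bind_rows(lapply(1:100, function(i) {
    hrs <- sort(sample(0:72, sample(3:73, 1)))
    tibble::tibble(
      hospitalization_id = sprintf("S%03d", i), hour = hrs,
      temp_c = runif(length(hrs), 35.5, 39.5)
    )
  }))
  got <- classify_subphenotype(series, refs)
  want <- classify_oracle(series, refs)
  m <- match(got$hospitalization_id, want$hospitalization_id)
  expect_identical(as.character(got$subphenotype), want$subphenotype[m])
})

test_that("noisy curves are recovered and the classifier is shift-consistent", {
  refs <- default_reference_trajectories()
  set.seed(11)
  labels <- sample(c("NT", "HT", "HFR", "HSR"), 200, replace = TRUE)
  series <- dplyr::bind_rows(lapply(seq_along(labels), function(i) {
    s <- ref_series(labels[i], sprintf("R%03d", i))
    s$temp_c <- s$temp_c + rnorm(73, 0, 0.2)
    s
  }))
  got <- classify_subphenotype(series, refs)
  m <- match(got$hospitalization_id, sprintf("R%03d", seq_along(labels)))
  expect_gte(mean(as.character(got$subphenotype) == labels[m]), 0.95)
  # mutually exclusive and exhaustive: one label per non-excluded encounter
  expect_identical(nrow(got), length(labels))
  expect_false(anyNA(got$subphenotype))

  # adding a constant to series and references leaves labels unchanged
  shifted_refs <- refs
  for (lab in c("NT", "HT", "HFR", "HSR")) shifted_refs[[lab]] <- refs[[lab]] + 2
  shifted_series <- series
  shifted_series$temp_c <- series$temp_c + 2
  got2 <- classify_subphenotype(shifted_series, reference_trajectories(shifted_refs))
  expect_identical(got2$subphenotype, got$subphenotype)
})

test_that("MSE depends only on the observed (hour, value) pairs", {
  refs <- default_reference_trajectories()
  s <- ref_series("HSR", hours = c(0, 10, 20, 40, 60))
  s$temp_c <- s$temp_c + c(0.1, -0.2, 0.15, 0, -0.1)
  shuffled <- s[c(3, 1, 5, 2, 4), ]
  expect_equal(classify_subphenotype(s, refs)$mse_HSR,
               classify_subphenotype(shuffled, refs)$mse_HSR)
})

test_that("the one-covariate reduced model matches the closed-form 2x2 odds ratio", {
  # constant covariates: the adjusted model collapses to y ~ subphenotype
  set.seed(3)
  n <- 400
  subph <- rep(c("NT", "HSR"), each = n / 2)
  y <- c(rbinom(n / 2, 1, 0.10), rbinom(n / 2, 1, 0.25))
  assignments <- tibble::tibble(
    hospitalization_id = sprintf("H%03d", 1:n),
    subphenotype = factor(subph, levels = c("NT", "HT", "HFR", "HSR"))
  )
  cohort <- tibble::tibble(
    hospitalization_id = assignments$hospitalization_id,
    age_at_admission = 60, sex_category = "female",
    race_category = "white", ethnicity_category = "non_hispanic",
    in_hospital_death = y == 1, ever_imv = FALSE
  )
  fit <- adjusted_outcome_model(assignments, cohort, "mortality")
  hsr <- fit[fit$subphenotype %in% "HSR", ]
  tab <- table(subph, y)
  or_2x2 <- (tab["HSR", "1"] * tab["NT", "0"]) / (tab["HSR", "0"] * tab["NT", "1"])
  expect_equal(hsr$odds_ratio, unname(or_2x2), tolerance = 1e-6)
  expect_equal(hsr$odds_ratio, exp(hsr$coefficient))
  expect_equal(hsr$ci_low, exp(hsr$coefficient - 1.96 * hsr$se))
})

test_that("degenerate outcome configurations are reported as fit failures", {
  assignments <- tibble::tibble(
    hospitalization_id = c("A", "B"),
    subphenotype = factor(c("NT", "HSR"), levels = c("NT", "HT", "HFR", "HSR"))
  )
  cohort <- tibble::tibble(
    hospitalization_id = c("A", "B"), age_at_admission = c(50, 60),
    sex_category = "female", race_category = "white",
    ethnicity_category = "non_hispanic",
    in_hospital_death = c(FALSE, FALSE), ever_imv = c(TRUE, TRUE)
  )
  expect_error(adjusted_outcome_model(assignments, cohort, "mortality"), "single class")

  # perfect separation: subphenotype determines the outcome exactly
  set.seed(4)
  n <- 200
  subph <- rep(c("NT", "HSR"), each = n / 2)
  sep_assign <- tibble::tibble(
    hospitalization_id = sprintf("S%03d", 1:n),
    subphenotype = factor(subph, levels = c("NT", "HT", "HFR", "HSR"))
  )
  sep_cohort <- tibble::tibble(
    hospitalization_id = sep_assign$hospitalization_id,
    age_at_admission = 60, sex_category = "female",
    race_category = "white", ethnicity_category = "non_hispanic",
    in_hospital_death = subph == "HSR", ever_imv = FALSE
  )
  expect_error(
    suppressWarnings(adjusted_outcome_model(sep_assign, sep_cohort, "mortality")),
    "separation"
  )
})
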