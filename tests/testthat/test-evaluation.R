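test_that("the AUC estimator handles separation, ties, and inversions", {
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "Both outcome classes")
  # complement identity on tie-free inputs
  set.seed(2)
  s <- runif(40)
  y <- rep(c(0, 1), 20)
  expect_equal(auc(s, y) + auc(-s, y), 1)
  # permutation invariance
  perm <- sample(40)
  expect_equal(auc(s[perm], y[perm]), auc(s, y))
})

test_that("the AUC equals the pairwise oracle exactly on random instances", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4)) # both classes guaranteed
    s <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
    expect_identical(auc(s, y), auc_pairwise(s, y))
  }
})

test_that("sample AUC matches a known binormal truth within 3 SE", {
  # scores ~ N(0,1) in controls, N(delta,1) in cases: AUC = pnorm(delta/sqrt(2))
  delta <- sqrt(2) * qnorm(0.80)
  set.seed(21)
  n1 <- 600; n0 <- 1400
  s <- c(rnorm(n0), rnorm(n1, delta))
  y <- c(rep(0, n0), rep(1, n1))
  a <- auc(s, y)
  # Hanley-McNeil standard error at the true AUC
  th <- 0.80
  q1 <- th / (2 - th); q2 <- 2 * th^2 / (1 + th)
  se <- sqrt((th * (1 - th) + (n1 - 1) * (q1 - th^2) + (n0 - 1) * (q2 - th^2)) / (n1 * n0))
  expect_lt(abs(a - th), 3 * se)
})

test_that("DeLong intervals behave and agree with an independent implementation", {
  set.seed(8)
  for (i in 1:5) {
    n <- 150
    y <- rbinom(n, 1, 0.35)
    y[1:2] <- c(0, 1)
    s <- rnorm(n, mean = 0.8 * y)
    ci <- auc_ci(s, y)
    a <- auc(s, y)
    expect_true(ci[1] <= a && a <= ci[2])
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE), method = "delong"))
    expect_equal(ci[1], as.numeric(ref[1]), tolerance = 1e-8)
    expect_equal(ci[2], as.numeric(ref[3]), tolerance = 1e-8)
  }
  # perfect separation: degenerate variance -> widest valid interval
  expect_warning(ci <- auc_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)),
                 "Degenerate")
  expect_identical(ci[2], 1)
})

test_that("the Brier score matches its closed forms", {
  expect_identical(brier(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_identical(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  # constant prediction p at prevalence pi: pi (1-p)^2 + (1-pi) p^2
  p <- 0.2
  y <- rep(c(1, 0), c(30, 70))
  expect_equal(brier(rep(p, 100), y), 0.3 * (1 - p)^2 + 0.7 * p^2)
  expect_error(brier(c(-0.1, 0.5), c(0, 1)), "probabilities")
})

test_that("calibration bins are equal-count, exhaustive, and honest", {
  set.seed(12)
  s <- runif(500)
  y <- rbinom(500, 1, s) # perfectly calibrated scores
  bins <- calibration_curve(s, y)
  expect_identical(nrow(bins), 10L)
  expect_identical(sum(bins$n), 500L)
  expect_true(all(abs(bins$n - 50) <= 1))
  # observed within 3 binomial SEs of predicted in every decile
  se <- sqrt(bins$mean_predicted * (1 - bins$mean_predicted) / bins$n)
  expect_true(all(abs(bins$mean_predicted - bins$observed_rate) < 3 * se + 1e-9))

  none <- calibration_curve(runif(50), rep(0, 50))
  expect_true(all(none$observed_rate == 0))

  expect_warning(small <- calibration_curve(runif(5), rbinom(5, 1, 0.5)), "bins")
  expect_identical(sum(small$n), 5L)
})

test_that("net benefit follows its definition and limiting identities", {
  # perfect classifier: NB equals prevalence at any threshold
  y <- rep(c(1, 0), c(25, 75))
  s <- y
  for (p_t in c(0.1, 0.3, 0.6)) {
    expect_equal(net_benefit(s, y, p_t)$net_benefit_model, 0.25)
  }
  # a score that calls everyone positive reproduces treat-all exactly
  nb <- net_benefit(rep(1, 100), y, 0.3)
  expect_identical(nb$net_benefit_model, nb$net_benefit_treat_all)
  expect_identical(nb$net_benefit_treat_none, 0)
  # treat-all tends to prevalence as the threshold vanishes
  expect_equal(net_benefit(s, y, 1e-9)$net_benefit_treat_all, 0.25, tolerance = 1e-6)
  expect_error(net_benefit(s, y, 1.2), "inside \\(0, 1\\)")
  # permutation invariance
  set.seed(3)
  s2 <- runif(100); perm <- sample(100)
  expect_equal(net_benefit(s2[perm], y[perm], 0.3), net_benefit(s2, y, 0.3))
})

test_that("site evaluation reports are complete, internally consistent, and round-trip", {
  res <- test_synth()
  cleaned <- apply_outlier_ranges(res$dataset)
  cohort <- discover_icu_cohort(cleaned$dataset)
  fm <- extract_features(cleaned$dataset, cohort)
  model <- train_mortality_model(
    fm, grid = data.frame(eta = 0.3, max_depth = 3L, nrounds = 30L), seed = 4
  )
  report <- evaluate_site(model, cleaned$dataset, cohort)

  expect_identical(report$n, nrow(cohort))
  expect_equal(report$prevalence, mean(cohort$in_hospital_death))
  scores <- predict_risk(model, fm)
  expect_equal(report$auc, auc(scores, fm$in_hospital_death))
  expect_equal(report$brier, brier(scores, fm$in_hospital_death))
  expect_true(0.3 %in% report$decision_curve$threshold)
  expect_true(all(report$decision_curve$net_benefit_treat_none == 0))
  expect_true(report$auc_ci[1] <= report$auc && report$auc <= report$auc_ci[2])

  dir <- withr::local_tempdir()
  write_evaluation_report(report, file.path(dir, "report.json"))
  back <- read_evaluation_report(file.path(dir, "report.json"))
  expect_equal(back$auc, report$auc, tolerance = 0)
  expect_equal(back$auc_ci, report$auc_ci, tolerance = 0)
  expect_equal(as.data.frame(back$decision_curve),
               as.data.frame(report$decision_curve), tolerance = 0)
  expect_equal(as.data.frame(back$calibration),
               as.data.frame(report$calibration), tolerance = 0)

  expect_error(evaluate_site(model, cleaned$dataset, cohort[0, ]), "Empty cohort")
})

test_that("ROC coordinates are monotone, anchored, and consistent with the AUC", {
  set.seed(5)
  s <- c(runif(60), runif(40) + 0.4)
  y <- rep(c(0, 1), c(60, 40))
  roc <- roc_curve(s, y)
  expect_identical(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_identical(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # trapezoidal area under the path equals the rank-based AUC (tie-free scores)
  area <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  expect_equal(area, auc(s, y))
})

test_that("report panels render and tables export", {
  set.seed(6)
  n <- 200
  y <- rbinom(n, 1, 0.3)
  y[1:2] <- c(0, 1)
  s <- plogis(qlogis(0.3) + 1.5 * y + rnorm(n))
  report <- structure(
    list(site = "demo", n = n, prevalence = mean(y),
         auc = auc(s, y), auc_ci = auc_ci(s, y), brier = brier(s, y),
         calibration = calibration_curve(s, y),
         decision_curve = decision_curve(s, y),
         roc = roc_curve(s, y)),
    class = "clif_evaluation_report"
  )
  panels <- plot_evaluation_report(report)
  expect_named(panels, c("roc", "calibration", "decision_curve"))
  for (p in panels) expect_s3_class(p, "ggplot")
  dir <- withr::local_tempdir()
  ggplot2::ggsave(file.path(dir, "roc.png"), panels$roc, width = 4, height = 4)
  expect_true(file.exists(file.path(dir, "roc.png")))
  write_evaluation_tables(report, file.path(dir, "tabs"))
  for (f in c("metrics.csv", "calibration.csv", "decision_curve.csv", "roc.csv")) {
    expect_true(file.exists(file.path(dir, "tabs", f)), info = f)
  }
})
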