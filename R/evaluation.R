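check_scores_labels <- function(scores, labels, require_both_classes = TRUE) {
  if (length(scores) != length(labels)) {
    rlang::abort("`scores` and `labels` must have equal length.")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    rlang::abort("`labels` must be binary 0/1.")
  }
  if (require_both_classes && length(unique(labels)) < 2) {
    rlang::abort("Both outcome classes must be present.")
  }
  labels
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive scores above a random negative, counting ties as one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placements: for each positive, the fraction of negatives it beats
# (ties half), and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(theta = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' DeLong 95% confidence interval for the AUC
#'
#' Analytic variance from the DeLong placement decomposition; the interval is
#' truncated to `[0, 1]`. A degenerate (zero) variance — e.g. perfect
#' separation — yields the widest valid interval consistent with the point
#' estimate, with a warning.
#'
#' @inheritParams auc
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`; always contains the point estimate.
#' @export
auc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- check_scores_labels(scores, labels)
  if (sum(labels == 1L) < 2 || sum(labels == 0L) < 2) {
    rlang::abort("DeLong interval needs at least 2 members of each class.")
  }
  pl <- delong_placements(scores, labels)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (v <= .Machine$double.eps) {
    rlang::warn("Degenerate DeLong variance; returning the widest valid interval.")
    return(c(min(pl$theta, 0), max(pl$theta, 1)))
  }
  lo <- max(0, pl$theta - z * sqrt(v))
  hi <- min(1, pl$theta + z * sqrt(v))
  c(lo, hi)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary 0/1 outcomes.
#' @return Brier score in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels, require_both_classes = FALSE)
  if (any(scores < 0 | scores > 1)) {
    rlang::abort("Brier score requires probabilities in [0, 1].")
  }
  mean((scores - labels)^2)
}

#' Calibration curve over equal-count risk bins
#'
#' Splits subjects into `n_bins` equal-count bins of predicted risk (deciles
#' by default) and reports the mean predicted risk and the observed event
#' rate per bin. With fewer subjects than bins, the bin count is reduced with
#' a warning.
#'
#' @inheritParams brier
#' @param n_bins Number of bins (default 10).
#' @return A tibble: `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10) {
  labels <- check_scores_labels(scores, labels, require_both_classes = FALSE)
  n <- length(scores)
  if (n < n_bins) {
    rlang::warn(sprintf("Only %d subjects; using %d calibration bins.", n, n))
    n_bins <- n
  }
  ord <- order(scores)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  tibble::tibble(scores = scores, labels = labels, bin = bin) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(scores),
      observed_rate = mean(labels),
      .groups = "drop"
    )
}

#' Net benefit at a decision threshold
#'
#' Classifying positive iff `score >= p_t`, the model's net benefit is
#' `TP/N - (FP/N) * p_t / (1 - p_t)`; the treat-all strategy has
#' `pi - (1 - pi) * p_t / (1 - p_t)` where `pi` is the event prevalence, and
#' treat-none is 0 by definition.
#'
#' @inheritParams brier
#' @param p_t Threshold probability in (0, 1).
#' @return A one-row tibble: `threshold`, `net_benefit_model`,
#'   `net_benefit_treat_all`, `net_benefit_treat_none`.
#' @export
net_benefit <- function(scores, labels, p_t) {
  labels <- check_scores_labels(scores, labels, require_both_classes = FALSE)
  stopifnot_scalar_number(p_t, "p_t")
  if (p_t <= 0 || p_t >= 1) rlang::abort("`p_t` must lie strictly inside (0, 1).")
  n <- length(labels)
  pos_call <- scores >= p_t
  tp <- sum(pos_call & labels == 1L)
  fp <- sum(pos_call & labels == 0L)
  prev <- mean(labels)
  w <- p_t / (1 - p_t)
  tibble::tibble(
    threshold = p_t,
    net_benefit_model = tp / n - (fp / n) * w,
    net_benefit_treat_all = prev - (1 - prev) * w,
    net_benefit_treat_none = 0
  )
}

#' Decision curve over a threshold grid
#'
#' @inheritParams net_benefit
#' @param p_t_grid Vector of thresholds in (0, 1).
#' @return A tibble with one [net_benefit()] row per threshold.
#' @export
decision_curve <- function(scores, labels, p_t_grid = seq(0.05, 0.5, by = 0.05)) {
  dplyr::bind_rows(lapply(p_t_grid, function(p) net_benefit(scores, labels, p)))
}

#' Evaluate the mortality model at one site
#'
#' The federated evaluation unit: every site runs this same function against
#' the shared model object and its local CLIF database and exchanges only the
#' resulting report. The report covers discrimination (AUC with DeLong 95%
#' CI), calibration (Brier score and equal-count calibration bins), and
#' clinical utility (the decision curve, always including the consortium
#' high-risk threshold of 0.3 with its treat-all and treat-none comparators).
#'
#' @param model A `clif_mortality_model`.
#' @param dataset A cleaned [clif_dataset].
#' @param cohort Cohort tibble from [discover_icu_cohort()].
#' @param spec The [feature_spec()] matching the model.
#' @param p_t_grid Decision thresholds; 0.3 is added if absent.
#' @return A `clif_evaluation_report` list: `site`, `n`, `prevalence`, `auc`,
#'   `auc_ci`, `brier`, `calibration` (tibble), `decision_curve` (tibble).
#' @export
evaluate_site <- function(model, dataset, cohort, spec = default_feature_spec(),
                          p_t_grid = seq(0.05, 0.5, by = 0.05)) {
  if (nrow(cohort) == 0) rlang::abort("Empty cohort; nothing to evaluate.")
  features <- extract_features(dataset, cohort, spec)
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols) > 0) {
    rlang::abort("Model and feature spec are incompatible.")
  }
  scores <- predict_risk(model, features)
  labels <- features$in_hospital_death
  p_t_grid <- sort(unique(c(p_t_grid, 0.3)))
  structure(
    list(
      site = dataset$site,
      n = length(labels),
      prevalence = mean(labels),
      auc = auc(scores, labels),
      auc_ci = auc_ci(scores, labels),
      brier = brier(scores, labels),
      calibration = calibration_curve(scores, labels),
      decision_curve = decision_curve(scores, labels, p_t_grid),
      roc = roc_curve(scores, labels)
    ),
    class = "clif_evaluation_report"
  )
}

#' @export
print.clif_evaluation_report <- function(x, ...) {
  nb03 <- x$decision_curve[x$decision_curve$threshold == 0.3, ]
  cat(sprintf(
    paste0("<clif_evaluation_report> site '%s' (n=%d, prevalence %.3f)\n",
           "  AUC %.3f [%.3f-%.3f], Brier %.3f\n",
           "  net benefit at p_t=0.3: model %.3f, treat-all %.3f, treat-none 0\n"),
    x$site, x$n, x$prevalence, x$auc, x$auc_ci[1], x$auc_ci[2], x$brier,
    nb03$net_benefit_model, nb03$net_benefit_treat_all
  ))
  invisible(x)
}

#' Serialize / restore an evaluation report as JSON
#'
#' Round-trips losslessly (full numeric precision).
#'
#' @param report A `clif_evaluation_report`.
#' @param path JSON path.
#' @return `path` invisibly; `read_evaluation_report` returns the report.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "clif_evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_evaluation_report
#' @export
read_evaluation_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$auc_ci <- as.numeric(x$auc_ci)
  x$calibration <- tibble::as_tibble(x$calibration)
  x$decision_curve <- tibble::as_tibble(x$decision_curve)
  x$roc <- tibble::as_tibble(x$roc)
  structure(x, class = "clif_evaluation_report")
}

#' ROC curve coordinates
#'
#' Sweeps the decision threshold over the observed scores and returns the
#' (false positive rate, true positive rate) path, including the (0,0) and
#' (1,1) endpoints.
#'
#' @inheritParams auc
#' @return A tibble: `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE) # one point per distinct threshold
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, cumsum(y)[keep] / sum(y)),
    fpr = c(0, cumsum(1 - y)[keep] / sum(1 - y))
  )
}

#' Plot an evaluation report as Fig-style panels
#'
#' Returns the three standard external-validation panels as ggplot objects:
#' the ROC curve (A), the calibration curve against the identity line (B),
#' and the decision curve with treat-all and treat-none comparators (C).
#' Save with `ggplot2::ggsave()` as SVG or PNG.
#'
#' @param report A `clif_evaluation_report` from [evaluate_site()].
#' @return Named list of ggplot objects: `roc`, `calibration`,
#'   `decision_curve`.
#' @export
plot_evaluation_report <- function(report) {
  stopifnot(inherits(report, "clif_evaluation_report"))
  roc <- ggplot2::ggplot(report$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s: AUC %.2f [%.2f-%.2f]", report$site,
                      report$auc, report$auc_ci[1], report$auc_ci[2]),
      x = "False positive rate", y = "True positive rate"
    ) +
    ggplot2::theme_minimal()
  calib <- ggplot2::ggplot(report$calibration,
                           ggplot2::aes(x = .data$mean_predicted, y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("%s: Brier %.3f", report$site, report$brier),
      x = "Mean predicted risk (decile)", y = "Observed event rate"
    ) +
    ggplot2::theme_minimal()
  dc_long <- tidyr::pivot_longer(
    report$decision_curve,
    cols = c("net_benefit_model", "net_benefit_treat_all", "net_benefit_treat_none"),
    names_to = "strategy", values_to = "net_benefit"
  )
  dc_long$strategy <- c(net_benefit_model = "model",
                        net_benefit_treat_all = "treat all",
                        net_benefit_treat_none = "treat none")[dc_long$strategy]
  dc <- ggplot2::ggplot(dc_long, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                              colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(0.05, max(dc_long$net_benefit)))) +
    ggplot2::labs(title = report$site, x = "Threshold probability",
                  y = "Net benefit", colour = NULL) +
    ggplot2::theme_minimal()
  list(roc = roc, calibration = calib, decision_curve = dc)
}

#' Export an evaluation report's tables as CSV
#'
#' Writes `metrics.csv` (n, prevalence, AUC and CI, Brier),
#' `calibration.csv`, `decision_curve.csv`, and `roc.csv` into a directory.
#'
#' @param report A `clif_evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_tables <- function(report, dir) {
  stopifnot(inherits(report, "clif_evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- tibble::tibble(
    site = report$site, n = report$n, prevalence = report$prevalence,
    auc = report$auc, auc_ci_low = report$auc_ci[1],
    auc_ci_high = report$auc_ci[2], brier = report$brier
  )
  readr::write_csv(metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(report$calibration, file.path(dir, "calibration.csv"))
  readr::write_csv(report$decision_curve, file.path(dir, "decision_curve.csv"))
  readr::write_csv(report$roc, file.path(dir, "roc.csv"))
  invisible(dir)
}
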