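#' Construct a per-site summary
#'
#' The consortium exchanges only these summary objects — never patient-level
#' rows. Counts are integers over the site's cohort; percentages are always
#' recomputed downstream from combined numerators and denominators.
#'
#' @param site Site label.
#' @param encounters Number of cohort encounters.
#' @param hospitals Number of hospitals contributing.
#' @param age_mean,age_sd Age mean and SD (years).
#' @param female_n Female encounter count.
#' @param race_n Named integer vector over `asian`, `black`, `white`, `other`.
#' @param ethnicity_n Named integer vector over `hispanic`, `non_hispanic`.
#' @param imv_n Encounters ever on invasive mechanical ventilation.
#' @param deaths_n In-hospital deaths.
#' @return A list of class `clif_site_summary`.
#' @export
site_summary <- function(site, encounters, hospitals, age_mean, age_sd,
                         female_n, race_n, ethnicity_n, imv_n, deaths_n) {
  counts <- c(female_n, race_n, ethnicity_n, imv_n, deaths_n)
  if (any(counts < 0) || encounters < 0) rlang::abort("Counts must be nonnegative.")
  if (any(counts > encounters)) {
    rlang::abort("Category counts cannot exceed the encounter count.")
  }
  structure(
    list(site = site, encounters = as.numeric(encounters),
         hospitals = as.numeric(hospitals),
         age_mean = age_mean, age_sd = age_sd,
         female_n = as.numeric(female_n),
         race_n = race_n[c("asian", "black", "white", "other")],
         ethnicity_n = ethnicity_n[c("hispanic", "non_hispanic")],
         imv_n = as.numeric(imv_n), deaths_n = as.numeric(deaths_n)),
    class = "clif_site_summary"
  )
}

#' @export
print.clif_site_summary <- function(x, ...) {
  cat(sprintf(
    "<clif_site_summary> %s: %.0f encounters, %.0f hospitals, %.0f deaths (%s%%)\n",
    x$site, x$encounters, x$hospitals, x$deaths_n,
    format_percent(100 * x$deaths_n / x$encounters)
  ))
  invisible(x)
}

#' Summarize a dataset's cohort in site-summary form
#'
#' Computes the Table-1-style characteristics for one site: encounter and
#' hospital counts, age mean/SD, and female, race, ethnicity, mechanical
#' ventilation, and in-hospital mortality counts over the cohort.
#'
#' @param dataset A validated [clif_dataset].
#' @param cohort Cohort membership tibble from [discover_icu_cohort()].
#' @return A `clif_site_summary`.
#' @export
dataset_summary <- function(dataset, cohort) {
  stopifnot(inherits(dataset, "clif_dataset"))
  if (nrow(cohort) == 0) rlang::abort("Empty cohort; nothing to summarize.")
  hospitals <- 1
  if ("adt" %in% names(dataset$tables) && "hospital_id" %in% names(dataset$tables$adt)) {
    adt <- dataset$tables$adt
    hospitals <- length(unique(stats::na.omit(
      adt$hospital_id[adt$hospitalization_id %in% cohort$hospitalization_id]
    )))
  }
  race <- norm_category(cohort$race_category)
  race[!race %in% c("asian", "black", "white")] <- "other"
  eth <- norm_category(cohort$ethnicity_category)
  eth[eth != "hispanic"] <- "non_hispanic"
  count_of <- function(x, lv) vapply(lv, function(l) sum(x == l, na.rm = TRUE), numeric(1))
  site_summary(
    site = dataset$site,
    encounters = nrow(cohort),
    hospitals = hospitals,
    age_mean = mean(cohort$age_at_admission),
    age_sd = stats::sd(cohort$age_at_admission),
    female_n = sum(norm_category(cohort$sex_category) == "female", na.rm = TRUE),
    race_n = count_of(race, c("asian", "black", "white", "other")),
    ethnicity_n = count_of(eth, c("hispanic", "non_hispanic")),
    imv_n = sum(cohort$ever_imv),
    deaths_n = sum(cohort$in_hospital_death)
  )
}

#' Combine per-site summaries into a consortium summary
#'
#' Counts are summed; percentages are left to the renderer, which always
#' recomputes them from the combined numerator and denominator. The combined
#' age mean is the encounter-weighted mean of site means; the combined age SD
#' is the pooled between+within approximation from each site's (n, mean, SD)
#' and is documented as approximate. Aggregation is associative: combining
#' sites in any grouping yields identical counts.
#'
#' @param summaries List of `clif_site_summary` objects (length >= 1).
#' @param site Label for the combined summary.
#' @return A `clif_site_summary` for the combined population.
#' @export
aggregate_sites <- function(summaries, site = "combined") {
  if (inherits(summaries, "clif_site_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, logical(1), "clif_site_summary")))
  if (length(summaries) == 1) {
    return(summaries[[1]])
  }
  get <- function(fld) vapply(summaries, function(s) s[[fld]], numeric(1))
  race_levels <- names(summaries[[1]]$race_n)
  eth_levels <- names(summaries[[1]]$ethnicity_n)
  for (s in summaries) {
    if (!identical(names(s$race_n), race_levels) ||
        !identical(names(s$ethnicity_n), eth_levels)) {
      rlang::abort("Mismatched race/ethnicity category sets across sites.")
    }
  }
  n <- get("encounters")
  mu <- get("age_mean")
  sdv <- get("age_sd")
  n_tot <- sum(n)
  mean_comb <- sum(n * mu) / n_tot
  # pooled between+within variance approximation
  var_comb <- (sum((n - 1) * sdv^2) + sum(n * (mu - mean_comb)^2)) / (n_tot - 1)
  race_comb <- Reduce(`+`, lapply(summaries, function(s) s$race_n))
  eth_comb <- Reduce(`+`, lapply(summaries, function(s) s$ethnicity_n))
  site_summary(
    site = site,
    encounters = n_tot,
    hospitals = sum(get("hospitals")),
    age_mean = mean_comb,
    age_sd = sqrt(var_comb),
    female_n = sum(get("female_n")),
    race_n = race_comb,
    ethnicity_n = eth_comb,
    imv_n = sum(get("imv_n")),
    deaths_n = sum(get("deaths_n"))
  )
}

#' Publication-style percentage rounding
#'
#' Percentages below 10 are shown to 2 significant figures (e.g. `"7.1"`,
#' `"0.07"`, `"3.6"`); 10 and above round to an integer (e.g. `"45"`).
#'
#' @param pct Numeric percentage values.
#' @return Character vector of formatted percentages (no `%` sign).
#' @export
format_percent <- function(pct) {
  vapply(pct, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p < 9.95) {
      format(signif(p, 2), trim = TRUE, scientific = FALSE)
    } else {
      sprintf("%.0f", p)
    }
  }, character(1))
}

fmt_n_pct <- function(n, denom) {
  sprintf("%d (%s%%)", as.integer(round(n)),
          format_percent(ifelse(denom > 0, 100 * n / denom, 0)))
}

#' Render site summaries as a publication-style characteristics table
#'
#' One column per site plus a combined column; `n (%)` cells with the
#' package's percentage rounding and `mean (SD)` cells to one decimal.
#'
#' @param summaries List of `clif_site_summary` objects.
#' @param combined_label Column label for the combined column.
#' @return A tibble with a `characteristic` column and one column per site
#'   plus the combined column.
#' @export
format_table_one <- function(summaries, combined_label = "Combined") {
  if (inherits(summaries, "clif_site_summary")) summaries <- list(summaries)
  cols <- summaries
  if (length(summaries) > 1) {
    cols <- c(summaries, list(aggregate_sites(summaries, site = combined_label)))
  }
  render <- function(s) {
    c(
      "Encounters, n" = sprintf("%d", as.integer(s$encounters)),
      "Hospitals, n" = sprintf("%d", as.integer(s$hospitals)),
      "Age (years), mean (SD)" = sprintf("%.1f (%.1f)", s$age_mean, s$age_sd),
      "Female n (%)" = fmt_n_pct(s$female_n, s$encounters),
      "Race: Asian n (%)" = fmt_n_pct(s$race_n[["asian"]], s$encounters),
      "Race: Black n (%)" = fmt_n_pct(s$race_n[["black"]], s$encounters),
      "Race: White n (%)" = fmt_n_pct(s$race_n[["white"]], s$encounters),
      "Race: Others n (%)" = fmt_n_pct(s$race_n[["other"]], s$encounters),
      "Ethnicity: Hispanic or Latino n (%)" = fmt_n_pct(s$ethnicity_n[["hispanic"]], s$encounters),
      "Ethnicity: Not Hispanic n (%)" = fmt_n_pct(s$ethnicity_n[["non_hispanic"]], s$encounters),
      "Mechanical Ventilation, n (%)" = fmt_n_pct(s$imv_n, s$encounters),
      "Hospital mortality, n (%)" = fmt_n_pct(s$deaths_n, s$encounters)
    )
  }
  cells <- lapply(cols, render)
  out <- tibble::tibble(characteristic = names(cells[[1]]))
  for (i in seq_along(cols)) {
    out[[cols[[i]]$site]] <- unname(cells[[i]])
  }
  out
}

#' Write / read site summaries as JSON
#'
#' @param summary A `clif_site_summary`.
#' @param path JSON path.
#' @return `path` invisibly; `read_site_summary` returns the summary.
#' @export
write_site_summary <- function(summary, path) {
  stopifnot(inherits(summary, "clif_site_summary"))
  x <- unclass(summary)
  x$race_n <- as.list(x$race_n)           # keep names in JSON objects
  x$ethnicity_n <- as.list(x$ethnicity_n)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_site_summary
#' @export
read_site_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  site_summary(x$site, x$encounters, x$hospitals, x$age_mean, x$age_sd,
               x$female_n, unlist(x$race_n), unlist(x$ethnicity_n),
               x$imv_n, x$deaths_n)
}

#' Example eight-site consortium summaries
#'
#' Per-site ICU cohort characteristics for an eight-health-system consortium
#' over the 2020--2021 study window, shipped as a CSV in `inst/extdata`. Used
#' to demonstrate and regression-test the federated aggregation arithmetic
#' (counts sum; percentages recompute from combined numerator/denominator).
#'
#' @return A list of eight `clif_site_summary` objects.
#' @export
example_consortium_summaries <- function() {
  path <- system.file("extdata", "consortium_site_summaries.csv", package = "clifr")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    site_summary(
      site = r$site, encounters = r$encounters, hospitals = r$hospitals,
      age_mean = r$age_mean, age_sd = r$age_sd, female_n = r$female_n,
      race_n = c(asian = r$asian_n, black = r$black_n,
                 white = r$white_n, other = r$other_n),
      ethnicity_n = c(hispanic = r$hispanic_n, non_hispanic = r$non_hispanic_n),
      imv_n = r$imv_n, deaths_n = r$deaths_n
    )
  })
}
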