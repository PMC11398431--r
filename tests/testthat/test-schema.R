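test_that("load_clif_table types conforming files and rejects malformed ones", {
  dir <- withr::local_tempdir()
  vit <- data.frame(
    hospitalization_id = c("H1", "H1"),
    recorded_dttm = c("2020-03-01T04:00:00", "2020-03-01T05:00:00"),
    vital_name = "PULSE",
    vital_category = "heart_rate",
    vital_value = c("72", "75")
  )
  pq <- file.path(dir, "vitals.parquet")
  arrow::write_parquet(vit, pq)

  tab <- load_clif_table(pq, "vitals")
  expect_s3_class(tab$recorded_dttm, "POSIXct")
  expect_identical(attr(tab$recorded_dttm, "tzone"), "UTC")
  expect_type(tab$vital_value, "double")
  expect_type(tab$hospitalization_id, "character")
  expect_length(attr(tab, "coercion_failures"), 0)

  # unknown table name
  expect_error(load_clif_table(pq, "respiratory_flowsheet"), "Unknown CLIF table")

  # missing required column
  arrow::write_parquet(vit[, setdiff(names(vit), "vital_category")], pq)
  expect_error(load_clif_table(pq, "vitals"), "vital_category")

  # CSV dialect with an unparseable datetime: reported, not dropped
  vit_bad <- vit
  vit_bad$recorded_dttm[2] <- "not-a-time"
  csv <- file.path(dir, "vitals.csv")
  write.csv(vit_bad, csv, row.names = FALSE)
  expect_warning(tab2 <- load_clif_table(csv, "vitals", max_failure_fraction = 0.5),
                 "failed type coercion")
  expect_identical(nrow(tab2), 2L)
  expect_true(is.na(tab2$recorded_dttm[2]))
  expect_identical(attr(tab2, "coercion_failures")[["recorded_dttm"]], 1L)
  # and errors above the tolerance
  expect_error(load_clif_table(csv, "vitals", max_failure_fraction = 0.1), "tolerance")
})

test_that("category mapping fills categories from names, idempotently", {
  vocab <- clif_vocabulary(
    "lab_category", permitted = c("hemoglobin", "albumin"),
    mapping = c("UCM_LAB HEMOGLOBIN - AUTOMATED" = "hemoglobin")
  )
  tab <- tibble::tibble(
    lab_name = c("UCM_LAB HEMOGLOBIN - AUTOMATED", "MYSTERY ASSAY"),
    lab_category = NA_character_
  )
  mapped <- apply_category_mapping(tab, vocab)
  expect_identical(mapped$lab_category, c("hemoglobin", NA))
  expect_identical(mapped$lab_name, tab$lab_name) # source names untouched
  expect_identical(attr(mapped, "unmapped")$n, 1L)
  expect_identical(attr(mapped, "unmapped")$names, "MYSTERY ASSAY")

  twice <- apply_category_mapping(mapped, vocab)
  expect_identical(twice$lab_category, mapped$lab_category)

  empty <- apply_category_mapping(tab[0, ], vocab)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "unmapped")$n, 0L)

  # mapping targets must be permissible
  expect_error(
    clif_vocabulary("lab_category", "hemoglobin", c("X" = "not_a_lab")),
    "not in the permitted set"
  )
})

test_that("schema invariants hold: _category columns need vocab and _name sibling", {
  cols <- rbind(
    data.frame(name = "hospitalization_id", type = "id", required = TRUE,
               vocabulary = NA_character_),
    data.frame(name = "thing_category", type = "category", required = TRUE,
               vocabulary = "vital_category")
  )
  expect_error(clif_table_schema("vitals", cols), "sibling")
  expect_silent(clif_table_schema("vitals", rbind(
    cols,
    data.frame(name = "thing_name", type = "free_text", required = FALSE,
               vocabulary = NA_character_)
  )))
})

test_that("a conforming synthetic dataset validates with zero violations", {
  res <- test_synth()
  report <- validate_dataset(res$dataset)
  expect_true(report$pass)
  expect_identical(nrow(report$violations), 0L)
})

test_that("the validator reports exactly the seeded violations, rule by rule", {
  res <- test_synth()
  ds <- res$dataset

  # seed k violations of each rule
  ds$tables$vitals$vital_category[c(10, 20, 30)] <- "pulse_rate_typo"   # 3 permitted_value
  ds$tables$labs$hospitalization_id[c(5, 6)] <- "H_ORPHAN"              # 2 referential_integrity
  ds$tables$patient$patient_id[2] <- ds$tables$patient$patient_id[1]    # key dup + orphan link
  ds$tables$adt$out_dttm[4] <- ds$tables$adt$in_dttm[4] - 3600          # 1 datetime_order

  report <- validate_dataset(ds)
  expect_false(report$pass)
  counts <- stats::setNames(report$counts$n, report$counts$rule)
  expect_identical(counts[["permitted_value"]], 3L)
  expect_identical(counts[["referential_integrity"]], 3L) # 2 orphan labs + 1 orphan patient link
  expect_identical(counts[["key_uniqueness"]], 1L)
  expect_identical(counts[["datetime_order"]], 1L)

  # dropping a required table is itself a violation
  ds2 <- res$dataset
  ds2$tables$labs <- NULL
  report2 <- validate_dataset(ds2)
  expect_identical(sum(report2$violations$rule == "required_table"), 1L)

  # report export round-trips through CSV and JSON
  dir <- withr::local_tempdir()
  write_validation_report(report, file.path(dir, "v.csv"))
  write_validation_report(report, file.path(dir, "v.json"))
  expect_identical(nrow(readr::read_csv(file.path(dir, "v.csv"), show_col_types = FALSE)),
                   nrow(report$violations))
  expect_false(jsonlite::read_json(file.path(dir, "v.json"))$pass)
})

test_that("a CLIF dataset round-trips through Parquet exactly", {
  res <- test_synth()
  dir <- withr::local_tempdir()
  write_clif_dataset(res$dataset, dir)
  back <- read_clif_dataset(dir, site = res$dataset$site)
  expect_setequal(names(back$tables), names(res$dataset$tables))
  for (nm in names(res$dataset$tables)) {
    orig <- as.data.frame(res$dataset$tables[[nm]])
    got <- as.data.frame(back$tables[[nm]][, names(orig)])
    attr(got, "coercion_failures") <- NULL
    expect_equal(got, orig, tolerance = 0, info = nm)
  }
})

test_that("dataset_summary matches generator ground truth", {
  res <- test_synth()
  gt <- res$ground_truth$encounters
  cohort <- discover_icu_cohort(res$dataset)
  ss <- dataset_summary(res$dataset, cohort)

  gtc <- gt[gt$qualifies, ]
  expect_identical(ss$encounters, as.numeric(nrow(gtc)))
  expect_identical(ss$deaths_n, as.numeric(sum(gtc$death)))
  expect_identical(ss$imv_n, as.numeric(sum(gtc$imv)))
  expect_identical(ss$female_n, as.numeric(sum(gtc$sex_category == "female")))
  expect_identical(unname(ss$race_n[["black"]]),
                   as.numeric(sum(gtc$race_category == "black")))
  expect_equal(ss$age_mean, mean(gtc$age))

  # configured mortality prevalence is recovered within binomial noise (3 SE)
  p <- res$config$mortality$target_prevalence
  se3 <- 3 * sqrt(p * (1 - p) / nrow(gtc))
  expect_lt(abs(ss$deaths_n / ss$encounters - p), se3 + 0.02) # + small shift from cohort conditioning

  expect_error(dataset_summary(res$dataset, cohort[0, ]), "Empty cohort")
})
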