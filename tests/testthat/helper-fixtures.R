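# Shared fixtures, built in code at test time.

# A small but fully featured synthetic dataset used by several test files.
test_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(
        n_encounters = 300, seed = 42,
        outlier_rate = 0.003, zero_temperature_fraction = 0.02
      )
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A tiny handcrafted dataset: three encounters with controlled ADT timing.
# H1 qualifies at every boundary exactly (age 18, ICU entry at 48 h,
# contiguous ICU stay 24 h split in two sub-hour-gap segments);
# H2 is underage; H3 enters the ICU too late.
handmade_dataset <- function() {
  patient <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    race_name = "WHITE", race_category = "white",
    ethnicity_name = "NOT HISPANIC", ethnicity_category = "non_hispanic",
    sex_name = c("F", "M", "F"), sex_category = c("female", "male", "female"),
    birth_date = utc(c("2002-06-01", "2002-07-15", "1960-01-01")),
    death_dttm = utc(c(NA, NA, NA))
  )
  hospitalization <- tibble::tibble(
    hospitalization_id = c("H1", "H2", "H3"),
    patient_id = c("P1", "P2", "P3"),
    admission_dttm = utc(c("2020-06-01 00:00", "2020-06-01 00:00", "2020-06-01 00:00")),
    discharge_dttm = utc(c("2020-06-05 00:00", "2020-06-05 00:00", "2020-06-08 00:00")),
    age_at_admission = c(18, 17.9, 60.5),
    discharge_name = c("HOME", "HOME", "EXPIRED"),
    discharge_category = c("home", "home", "expired")
  )
  adt <- tibble::tibble(
    hospitalization_id = c("H1", "H1", "H1", "H2", "H3"),
    hospital_id = "HOSP01",
    in_dttm = utc(c(
      "2020-06-01 00:00", # H1 ward
      "2020-06-03 00:00", # H1 ICU part 1 (entry exactly 48 h after admission)
      "2020-06-03 12:30", # H1 ICU part 2 after a 30-min gap
      "2020-06-01 01:00", # H2 ICU
      "2020-06-03 00:30"  # H3 ICU entry at 48.5 h
    )),
    out_dttm = utc(c(
      "2020-06-03 00:00",
      "2020-06-03 12:00",
      "2020-06-04 00:00", # contiguous ICU span exactly 24 h
      "2020-06-03 12:00",
      "2020-06-06 00:00"
    )),
    location_name = c("WARD", "ICU", "ICU", "ICU", "ICU"),
    location_category = c("ward", "icu", "icu", "icu", "icu")
  )
  vitals <- tibble::tibble(
    hospitalization_id = "H1",
    recorded_dttm = utc("2020-06-03 01:00"),
    vital_name = "PULSE", vital_category = "heart_rate", vital_value = 70
  )
  labs <- tibble::tibble(
    hospitalization_id = "H1",
    lab_order_dttm = utc("2020-06-03 01:00"),
    lab_result_dttm = utc("2020-06-03 02:00"),
    lab_name = "ALBUMIN", lab_category = "albumin",
    lab_value_numeric = 3.1, reference_unit = "g/dL"
  )
  clif_dataset(
    list(patient = patient, hospitalization = hospitalization, adt = adt,
         vitals = vitals, labs = labs),
    site = "handmade"
  )
}

make_cohort_row <- function(id = "H1", entry = utc("2020-06-03 00:00")) {
  tibble::tibble(
    hospitalization_id = id, patient_id = "P1",
    icu_entry_dttm = entry, icu_exit_dttm = entry + 72 * 3600,
    age_at_admission = 60, sex_category = "female",
    race_category = "white", ethnicity_category = "non_hispanic",
    in_hospital_death = FALSE, ever_imv = FALSE
  )
}

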