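# Independent oracles used across tests. These deliberately use naive
# O(n^2) / per-case loops so they share no code path with the package.

# Pairwise Mann-Whitney AUC: loop over every positive-negative pair.
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Naive per-encounter, per-label mean squared error classifier.
classify_oracle <- function(series, refset) {
  refdf <- as.data.frame(refset)
  ids <- unique(series$hospitalization_id)
  out <- data.frame(hospitalization_id = ids, subphenotype = NA_character_)
  for (i in seq_along(ids)) {
    sub <- series[series$hospitalization_id == ids[i], ]
    mse <- sapply(c("NT", "HT", "HFR", "HSR"), function(lab) {
      ref_vals <- refdf[[lab]][match(sub$hour, refdf$hour)]
      mean((sub$temp_c - ref_vals)^2)
    })
    out$subphenotype[i] <- c("NT", "HT", "HFR", "HSR")[which.min(mse)]
  }
  out
}

# Naive feature aggregation: direct filtering per encounter and feature.
extract_features_oracle <- function(dataset, cohort, spec) {
  out <- cohort[, "hospitalization_id", drop = FALSE]
  fs <- spec$features
  for (j in seq_len(nrow(fs))) {
    vals <- rep(NA_real_, nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      entry <- cohort$icu_entry_dttm[i]
      if (fs$stream[j] == "vitals") {
        tab <- dataset$tables$vitals
        sel <- tab$hospitalization_id == cohort$hospitalization_id[i] &
          tab$vital_category == fs$category[j] &
          tab$recorded_dttm >= entry &
          tab$recorded_dttm < entry + 24 * 3600 &
          !is.na(tab$vital_value)
        x <- tab$vital_value[sel]
      } else {
        tab <- dataset$tables$labs
        sel <- tab$hospitalization_id == cohort$hospitalization_id[i] &
          tab$lab_category == fs$category[j] &
          tab$lab_result_dttm >= entry &
          tab$lab_result_dttm < entry + 24 * 3600 &
          !is.na(tab$lab_value_numeric)
        x <- tab$lab_value_numeric[sel]
      }
      if (length(x) > 0) {
        vals[i] <- switch(fs$stat[j], min = min(x), max = max(x), mean = mean(x))
      }
    }
    out[[fs$name[j]]] <- vals
  }
  out
}
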