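#' Assemble a CLIF dataset
#'
#' A `clif_dataset` is a named collection of typed longitudinal tables keyed
#' by patient and hospitalization identifiers, plus a site label. All
#' datetimes are stored timezone-aware in UTC; files carrying other zones are
#' converted on load.
#'
#' @param tables Named list of data frames; names must be registered table
#'   names (see [clif_table_names()]).
#' @param site Site label attached to summaries and reports.
#' @param registry Schema registry used to check table names.
#' @return An object of class `clif_dataset`.
#' @export
clif_dataset <- function(tables, site = "unlabelled",
                         registry = clif_schema_registry()) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  unknown <- setdiff(names(tables), names(registry))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown CLIF table name(s): %s", paste(unknown, collapse = ", ")))
  }
  tables <- lapply(tables, tibble::as_tibble)
  structure(
    list(tables = tables, site = site, timezone = "UTC"),
    class = "clif_dataset"
  )
}

#' @export
print.clif_dataset <- function(x, ...) {
  cat(sprintf("<clif_dataset> site '%s': %d tables\n", x$site, length(x$tables)))
  for (nm in names(x$tables)) {
    cat(sprintf("  %-28s %6d rows\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

coerce_column <- function(x, type) {
  switch(type,
    id = as.character(x),
    free_text = as.character(x),
    category = as.character(x),
    numeric = suppressWarnings(as.numeric(x)),
    datetime = if (is_datetime(x)) as_utc(x) else parse_datetime_utc(as.character(x)),
    rlang::abort(sprintf("Unknown semantic type '%s'.", type))
  )
}

#' Load one CLIF table from Parquet or CSV
#'
#' Reads the file, checks it against the registered schema, and coerces every
#' declared column to its semantic type (ids and categories to character,
#' numerics to double, datetimes to UTC `POSIXct`). Values that fail coercion
#' (e.g. unparseable datetimes) become `NA` and are reported through the
#' `"coercion_failures"` attribute — never silently dropped. If the failure
#' fraction in any column exceeds `max_failure_fraction`, loading errors.
#'
#' @param path Path to a `.parquet` or `.csv` file.
#' @param table_name Registered CLIF table name.
#' @param registry Schema registry, by default [clif_schema_registry()].
#' @param max_failure_fraction Tolerated per-column coercion-failure fraction
#'   before loading aborts (default 0, i.e. any failure is reported but only
#'   a fraction above this errors).
#' @return A tibble with attribute `"coercion_failures"` (named integer,
#'   failures per column).
#' @export
load_clif_table <- function(path, table_name, registry = clif_schema_registry(),
                            max_failure_fraction = 0.05) {
  if (!table_name %in% names(registry)) {
    rlang::abort(sprintf("Unknown CLIF table name '%s'.", table_name))
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path))
  }
  schema <- registry[[table_name]]
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    parquet = arrow::read_parquet(path),
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    rlang::abort(sprintf("Unsupported file extension '.%s' (use Parquet or CSV).", ext))
  )
  raw <- tibble::as_tibble(raw)
  required_cols <- schema$columns$name[schema$columns$required]
  missing_cols <- setdiff(required_cols, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf(
      "Table '%s' is missing required column(s): %s",
      table_name, paste(missing_cols, collapse = ", ")
    ))
  }
  failures <- integer(0)
  for (i in seq_len(nrow(schema$columns))) {
    col <- schema$columns$name[i]
    if (!col %in% names(raw)) next
    before_na <- is.na(raw[[col]])
    coerced <- coerce_column(raw[[col]], schema$columns$type[i])
    n_fail <- sum(is.na(coerced) & !before_na)
    if (n_fail > 0) {
      failures[col] <- n_fail
      frac <- n_fail / nrow(raw)
      if (frac > max_failure_fraction) {
        rlang::abort(sprintf(
          "Table '%s', column '%s': %d of %d values (%.1f%%) failed type coercion (tolerance %.1f%%).",
          table_name, col, n_fail, nrow(raw), 100 * frac, 100 * max_failure_fraction
        ))
      }
      rlang::warn(sprintf(
        "Table '%s', column '%s': %d value(s) failed type coercion and were set to NA.",
        table_name, col, n_fail
      ))
    }
    raw[[col]] <- coerced
  }
  attr(raw, "coercion_failures") <- failures
  raw
}

#' Write / read a CLIF dataset as a directory of table files
#'
#' Tables are written as `clif_<table_name>.parquet` (the canonical format)
#' or `clif_<table_name>.csv` (RFC 4180, UTF-8, ISO-8601 datetimes).
#'
#' @param dataset A [clif_dataset].
#' @param dir Directory to write to (created if needed).
#' @param format `"parquet"` (default) or `"csv"`.
#' @return `write_clif_dataset` returns the directory invisibly;
#'   `read_clif_dataset` returns a [clif_dataset].
#' @export
write_clif_dataset <- function(dataset, dir, format = c("parquet", "csv")) {
  stopifnot(inherits(dataset, "clif_dataset"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset$tables)) {
    path <- file.path(dir, sprintf("clif_%s.%s", nm, format))
    if (format == "parquet") {
      arrow::write_parquet(dataset$tables[[nm]], path)
    } else {
      readr::write_csv(dataset$tables[[nm]], path)
    }
  }
  invisible(dir)
}

#' @rdname write_clif_dataset
#' @param site Site label for the loaded dataset.
#' @param registry Schema registry.
#' @export
read_clif_dataset <- function(dir, site = basename(dir),
                              registry = clif_schema_registry()) {
  files <- list.files(dir, pattern = "^clif_.*\\.(parquet|csv)$", full.names = TRUE)
  if (length(files) == 0) {
    rlang::abort(sprintf("No clif_<table>.parquet/csv files found in '%s'.", dir))
  }
  tables <- list()
  for (f in files) {
    nm <- sub("^clif_", "", tools::file_path_sans_ext(basename(f)))
    if (!nm %in% names(registry)) {
      rlang::warn(sprintf("Skipping unregistered table file '%s'.", basename(f)))
      next
    }
    tables[[nm]] <- load_clif_table(f, nm, registry)
  }
  clif_dataset(tables, site = site, registry = registry)
}

new_validation_report <- function(violations) {
  violations <- tibble::as_tibble(violations)
  counts <- dplyr::count(violations, .data$rule, name = "n")
  structure(
    list(
      violations = violations,
      counts = counts,
      pass = nrow(violations) == 0
    ),
    class = "clif_validation_report"
  )
}

violation_row <- function(table, row_locator, column, rule, message) {
  tibble::tibble(
    table = table, row_locator = as.character(row_locator),
    column = column, rule = rule, message = message
  )
}

empty_violations <- function() {
  violation_row(character(0), character(0), character(0), character(0), character(0))
}

#' @export
print.clif_validation_report <- function(x, ...) {
  cat(sprintf("<clif_validation_report> %s: %d violation(s)\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$violations)))
  if (nrow(x$counts) > 0) print(x$counts)
  invisible(x)
}

#' Validate a CLIF dataset against schema and vocabularies
#'
#' Runs the conformance rules over every loaded table:
#' \itemize{
#'   \item `required_table`: all required tables are present;
#'   \item `required_column`: required columns are present and non-missing
#'     key/link identifiers;
#'   \item `permitted_value`: every non-missing `_category` value belongs to
#'     its vocabulary's permissible set (case-insensitive);
#'   \item `key_uniqueness`: declared key column sets are unique and non-null;
#'   \item `referential_integrity`: every `hospitalization_id` in a
#'     longitudinal table exists in `hospitalization`, and every `patient_id`
#'     exists in `patient`;
#'   \item `datetime_order`: declared interval orderings hold (ADT
#'     `out_dttm >= in_dttm`, hospitalization `discharge_dttm >=
#'     admission_dttm`).
#' }
#' Violations are data, not exceptions: the report lists each one with a row
#' locator and the dataset passes iff no violation of a required rule exists
#' (all rules above are required).
#'
#' @param dataset A [clif_dataset].
#' @param registry Schema registry.
#' @param vocabularies Named list of [clif_vocabulary] objects.
#' @return A `clif_validation_report` with fields `violations` (tibble),
#'   `counts` (per rule), and `pass`.
#' @export
validate_dataset <- function(dataset, registry = clif_schema_registry(),
                             vocabularies = clif_vocabularies()) {
  stopifnot(inherits(dataset, "clif_dataset"))
  v <- list(empty_violations())

  required_tables <- names(registry)[vapply(registry, function(s) s$required, logical(1))]
  for (tn in setdiff(required_tables, names(dataset$tables))) {
    v[[length(v) + 1L]] <- violation_row(tn, NA, NA_character_, "required_table",
                                         sprintf("Required table '%s' is absent.", tn))
  }

  hosp_ids <- if ("hospitalization" %in% names(dataset$tables)) {
    dataset$tables$hospitalization$hospitalization_id
  } else character(0)
  pat_ids <- if ("patient" %in% names(dataset$tables)) {
    dataset$tables$patient$patient_id
  } else character(0)

  for (tn in names(dataset$tables)) {
    tab <- dataset$tables[[tn]]
    schema <- registry[[tn]]
    if (is.null(schema)) next

    required_cols <- schema$columns$name[schema$columns$required]
    for (col in setdiff(required_cols, names(tab))) {
      v[[length(v) + 1L]] <- violation_row(tn, NA, col, "required_column",
                                           sprintf("Required column '%s' is absent.", col))
    }

    # permitted values for `_category` columns bound to a vocabulary
    cat_specs <- schema$columns[!is.na(schema$columns$vocabulary), , drop = FALSE]
    for (i in seq_len(nrow(cat_specs))) {
      col <- cat_specs$name[i]
      if (!col %in% names(tab)) next
      vocab <- vocabularies[[cat_specs$vocabulary[i]]]
      if (is.null(vocab)) next
      vals <- norm_category(tab[[col]])
      bad <- which(!is.na(tab[[col]]) & !(vals %in% vocab$permitted))
      for (r in bad) {
        v[[length(v) + 1L]] <- violation_row(
          tn, r, col, "permitted_value",
          sprintf("Value '%s' is not a permissible %s value.", tab[[col]][r], vocab$element)
        )
      }
    }

    # key uniqueness and non-null keys
    if (length(schema$keys) > 0 && all(schema$keys %in% names(tab))) {
      key_df <- tab[, schema$keys, drop = FALSE]
      null_rows <- which(!stats::complete.cases(key_df))
      for (r in null_rows) {
        v[[length(v) + 1L]] <- violation_row(
          tn, r, paste(schema$keys, collapse = "+"), "key_uniqueness",
          "Missing value in key column(s)."
        )
      }
      dup_rows <- which(duplicated(key_df))
      for (r in dup_rows) {
        v[[length(v) + 1L]] <- violation_row(
          tn, r, paste(schema$keys, collapse = "+"), "key_uniqueness",
          "Duplicate key."
        )
      }
    }

    # referential integrity
    if (tn != "hospitalization" && "hospitalization_id" %in% names(tab) &&
        "hospitalization" %in% names(dataset$tables)) {
      orphan <- which(!is.na(tab$hospitalization_id) &
                        !(tab$hospitalization_id %in% hosp_ids))
      for (r in orphan) {
        v[[length(v) + 1L]] <- violation_row(
          tn, r, "hospitalization_id", "referential_integrity",
          sprintf("hospitalization_id '%s' not found in hospitalization table.",
                  tab$hospitalization_id[r])
        )
      }
    }
    if (tn != "patient" && "patient_id" %in% names(tab) &&
        "patient" %in% names(dataset$tables)) {
      orphan <- which(!is.na(tab$patient_id) & !(tab$patient_id %in% pat_ids))
      for (r in orphan) {
        v[[length(v) + 1L]] <- violation_row(
          tn, r, "patient_id", "referential_integrity",
          sprintf("patient_id '%s' not found in patient table.", tab$patient_id[r])
        )
      }
    }

    # datetime monotonicity for declared intervals
    interval_cols <- switch(tn,
      adt = c("in_dttm", "out_dttm"),
      hospitalization = c("admission_dttm", "discharge_dttm"),
      NULL
    )
    if (!is.null(interval_cols) && all(interval_cols %in% names(tab))) {
      bad <- which(!is.na(tab[[interval_cols[1]]]) & !is.na(tab[[interval_cols[2]]]) &
                     tab[[interval_cols[2]]] < tab[[interval_cols[1]]])
      for (r in bad) {
        v[[length(v) + 1L]] <- violation_row(
          tn, r, paste(interval_cols, collapse = "/"), "datetime_order",
          sprintf("%s precedes %s.", interval_cols[2], interval_cols[1])
        )
      }
    }
  }

  new_validation_report(dplyr::bind_rows(v))
}

#' Export a validation report
#'
#' @param report A `clif_validation_report`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "clif_validation_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(report$violations, path)
  } else if (ext == "json") {
    jsonlite::write_json(
      list(pass = report$pass, counts = report$counts, violations = report$violations),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    rlang::abort("Use a .csv or .json path.")
  }
  invisible(path)
}
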