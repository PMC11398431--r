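#' @title CLIF table schema registry
#' @description
#' CLIF organizes critical-care EHR data into 23 clinically relevant
#' longitudinal tables linked by patient and hospitalization identifiers.
#' The registry describes, for each table, its columns (name, semantic type,
#' required flag, controlled vocabulary for `_category` columns), its key
#' columns, and its foreign-key links. Field-level schemas are fully
#' specified for the tables the bundled analyses use (patient,
#' hospitalization, adt, vitals, labs, respiratory_support,
#' medication_admin_continuous, scores); the remaining tables carry minimal
#' schemas (keys, a datetime, and a `_name`/`_category` pair) and the
#' registry is extensible via [clif_table_schema()].
#' @name clif-schema
NULL

# Semantic types understood by the loader/validator.
SEMANTIC_TYPES <- c("id", "datetime", "numeric", "category", "free_text")

column_spec <- function(name, type, required = TRUE, vocabulary = NULL) {
  stopifnot(type %in% SEMANTIC_TYPES)
  if (grepl("_category$", name)) {
    if (is.null(vocabulary)) {
      rlang::abort(sprintf("`_category` column '%s' must reference a vocabulary.", name))
    }
  }
  tibble::tibble(
    name = name, type = type, required = required,
    vocabulary = if (is.null(vocabulary)) NA_character_ else vocabulary
  )
}

#' Define a CLIF table schema
#'
#' @param table_name Table identifier (lower_snake_case).
#' @param columns A data frame of column specs as built by the registry
#'   (columns `name`, `type`, `required`, `vocabulary`).
#' @param keys Character vector of columns that must be jointly unique and
#'   non-missing within the table. May be empty for event streams.
#' @param links Character vector of foreign keys (`patient_id` and/or
#'   `hospitalization_id`).
#' @param required Is the table required for a dataset to validate?
#' @return An object of class `clif_table_schema`.
#' @export
clif_table_schema <- function(table_name, columns, keys = character(),
                              links = character(), required = FALSE) {
  stopifnot(is.character(table_name), length(table_name) == 1L, is.data.frame(columns))
  # every `_category` column must have a sibling `_name` column
  cats <- grep("_category$", columns$name, value = TRUE)
  sibs <- sub("_category$", "_name", cats)
  missing_sib <- sibs[!sibs %in% columns$name]
  if (length(missing_sib) > 0) {
    rlang::abort(sprintf(
      "Table '%s': `_category` columns without sibling `_name` columns: %s",
      table_name, paste(missing_sib, collapse = ", ")
    ))
  }
  bad_key <- keys[!keys %in% columns$name]
  if (length(bad_key) > 0) {
    rlang::abort(sprintf("Table '%s': key columns not in schema: %s",
                         table_name, paste(bad_key, collapse = ", ")))
  }
  structure(
    list(table_name = table_name, columns = tibble::as_tibble(columns),
         keys = keys, links = links, required = required),
    class = "clif_table_schema"
  )
}

#' @export
print.clif_table_schema <- function(x, ...) {
  cat(sprintf("<clif_table_schema> %s (%d columns; keys: %s; links: %s)%s\n",
              x$table_name, nrow(x$columns),
              if (length(x$keys)) paste(x$keys, collapse = "+") else "none",
              if (length(x$links)) paste(x$links, collapse = ", ") else "none",
              if (x$required) " [required]" else ""))
  invisible(x)
}

# A minimal longitudinal schema: hospitalization link, an event datetime and
# a `_name`/`_category` pair. Used for the tables whose full column lists the
# bundled analyses do not need.
minimal_schema <- function(table_name, stem, vocabulary = NA_character_) {
  cols <- rbind(
    column_spec("hospitalization_id", "id"),
    column_spec("recorded_dttm", "datetime"),
    tibble::tibble(name = paste0(stem, "_name"), type = "free_text",
                   required = FALSE, vocabulary = NA_character_),
    tibble::tibble(name = paste0(stem, "_category"), type = "category",
                   required = FALSE, vocabulary = vocabulary)
  )
  clif_table_schema(table_name, cols, keys = character(),
                    links = "hospitalization_id", required = FALSE)
}

#' Default CLIF schema registry
#'
#' @return Named list of [clif_table_schema] objects keyed by table name.
#' @seealso [clif_vocabularies()] for the matching controlled vocabularies.
#' @export
clif_schema_registry <- function() {
  reg <- list(
    clif_table_schema(
      "patient",
      rbind(
        column_spec("patient_id", "id"),
        column_spec("race_name", "free_text", required = FALSE),
        column_spec("race_category", "category", vocabulary = "race_category"),
        column_spec("ethnicity_name", "free_text", required = FALSE),
        column_spec("ethnicity_category", "category", vocabulary = "ethnicity_category"),
        column_spec("sex_name", "free_text", required = FALSE),
        column_spec("sex_category", "category", vocabulary = "sex_category"),
        column_spec("birth_date", "datetime", required = FALSE),
        column_spec("death_dttm", "datetime", required = FALSE)
      ),
      keys = "patient_id", links = "patient_id", required = TRUE
    ),
    clif_table_schema(
      "hospitalization",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("patient_id", "id"),
        column_spec("admission_dttm", "datetime"),
        column_spec("discharge_dttm", "datetime"),
        column_spec("age_at_admission", "numeric"),
        column_spec("discharge_name", "free_text", required = FALSE),
        column_spec("discharge_category", "category", vocabulary = "discharge_category")
      ),
      keys = "hospitalization_id",
      links = c("patient_id", "hospitalization_id"), required = TRUE
    ),
    clif_table_schema(
      "adt",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("hospital_id", "id", required = FALSE),
        column_spec("in_dttm", "datetime"),
        column_spec("out_dttm", "datetime"),
        column_spec("location_name", "free_text", required = FALSE),
        column_spec("location_category", "category", vocabulary = "location_category")
      ),
      keys = c("hospitalization_id", "in_dttm"),
      links = "hospitalization_id", required = TRUE
    ),
    clif_table_schema(
      "vitals",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("recorded_dttm", "datetime"),
        column_spec("vital_name", "free_text", required = FALSE),
        column_spec("vital_category", "category", vocabulary = "vital_category"),
        column_spec("vital_value", "numeric")
      ),
      keys = character(), links = "hospitalization_id", required = TRUE
    ),
    clif_table_schema(
      "labs",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("lab_order_dttm", "datetime", required = FALSE),
        column_spec("lab_result_dttm", "datetime"),
        column_spec("lab_name", "free_text", required = FALSE),
        column_spec("lab_category", "category", vocabulary = "lab_category"),
        column_spec("lab_value_numeric", "numeric"),
        column_spec("reference_unit", "free_text", required = FALSE)
      ),
      keys = character(), links = "hospitalization_id", required = TRUE
    ),
    clif_table_schema(
      "respiratory_support",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("recorded_dttm", "datetime"),
        column_spec("device_name", "free_text", required = FALSE),
        column_spec("device_category", "category", vocabulary = "device_category"),
        column_spec("mode_name", "free_text", required = FALSE),
        column_spec("mode_category", "category", required = FALSE, vocabulary = "mode_category"),
        column_spec("fio2_set", "numeric", required = FALSE),
        column_spec("peep_set", "numeric", required = FALSE)
      ),
      keys = character(), links = "hospitalization_id", required = FALSE
    ),
    clif_table_schema(
      "medication_admin_continuous",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("admin_dttm", "datetime"),
        column_spec("med_name", "free_text", required = FALSE),
        column_spec("med_category", "category", vocabulary = "med_category"),
        column_spec("med_dose", "numeric"),
        column_spec("med_dose_unit", "free_text", required = FALSE)
      ),
      keys = character(), links = "hospitalization_id", required = FALSE
    ),
    clif_table_schema(
      "scores",
      rbind(
        column_spec("hospitalization_id", "id"),
        column_spec("recorded_dttm", "datetime"),
        column_spec("score_name", "free_text", required = FALSE),
        column_spec("score_category", "category", vocabulary = "score_category"),
        column_spec("score_value", "numeric")
      ),
      keys = character(), links = "hospitalization_id", required = FALSE
    ),
    # Minimal schemas for the remaining tables of the entity-relationship
    # model; their full column lists are site-extensible.
    minimal_schema("admission_diagnosis", "diagnosis"),
    minimal_schema("provider", "provider"),
    minimal_schema("dialysis", "dialysis"),
    minimal_schema("intake_output", "fluid"),
    minimal_schema("procedures", "procedure"),
    minimal_schema("therapy_session", "therapy"),
    minimal_schema("therapy_details", "therapy_detail"),
    minimal_schema("position", "position"),
    minimal_schema("ecmo_mcs", "support"),
    minimal_schema("microbiology_culture", "organism"),
    minimal_schema("sensitivity", "antibiotic"),
    minimal_schema("microbiology_nonculture", "test"),
    minimal_schema("medication_orders", "med", vocabulary = "med_category"),
    minimal_schema("medication_admin_intermittent", "med", vocabulary = "med_category")
  )
  stats::setNames(reg, vapply(reg, function(s) s$table_name, character(1)))
}

#' Names of the registered CLIF tables
#' @param registry A schema registry, by default [clif_schema_registry()].
#' @return Character vector of table names.
#' @export
clif_table_names <- function(registry = clif_schema_registry()) {
  names(registry)
}
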