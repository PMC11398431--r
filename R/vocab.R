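#' Construct an mCIDE controlled vocabulary
#'
#' CLIF pairs every standardized `_category` column with a raw `_name` column:
#' the `_name` preserves the source EHR label verbatim while the `_category`
#' holds one of a limited set of permissible values (a minimum Common ICU Data
#' Element, mCIDE). A `clif_vocabulary` bundles one element's permissible set
#' with an optional site-specific mapping from source names to categories.
#'
#' Permissible values are stored lower_snake_case and compared
#' case-insensitively; duplicates (after normalization) are an error.
#'
#' @param element Identifier of the vocabulary element, e.g. `"lab_category"`.
#' @param permitted Character vector of permissible category values.
#' @param mapping Named character vector: names are source `_name` strings,
#'   values are the categories they map to. Every target must be permitted.
#' @return An object of class `clif_vocabulary`.
#' @examples
#' vocab <- clif_vocabulary(
#'   "lab_category",
#'   permitted = c("hemoglobin", "albumin"),
#'   mapping = c("UCM_LAB HEMOGLOBIN - AUTOMATED" = "hemoglobin")
#' )
#' @export
clif_vocabulary <- function(element, permitted, mapping = character()) {
  stopifnot(is.character(element), length(element) == 1L)
  permitted <- norm_category(permitted)
  if (anyDuplicated(permitted)) {
    rlang::abort(sprintf("Vocabulary '%s' has duplicate permitted values after case normalization.", element))
  }
  mapping <- vapply(mapping, as.character, character(1))
  if (length(mapping) > 0) {
    if (is.null(names(mapping)) || any(names(mapping) == "")) {
      rlang::abort("`mapping` must be a named character vector (source_name -> category).")
    }
    bad <- !(norm_category(mapping) %in% permitted)
    if (any(bad)) {
      rlang::abort(sprintf(
        "Vocabulary '%s': mapping targets not in the permitted set: %s",
        element, paste(unique(mapping[bad]), collapse = ", ")
      ))
    }
    mapping[] <- norm_category(mapping)
  }
  structure(
    list(element = element, permitted = permitted, mapping = mapping),
    class = "clif_vocabulary"
  )
}

#' @export
print.clif_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<clif_vocabulary> %s: %d permitted values, %d mapped source names\n",
    x$element, length(x$permitted), length(x$mapping)
  ))
  invisible(x)
}

#' Default CLIF controlled vocabularies
#'
#' Returns the package's built-in permissible-value sets for the `_category`
#' elements used by the case-study tables. The sets cover common vitals, labs,
#' hospital locations, respiratory-support devices and modes, continuous
#' medications, demographic categories, and discharge dispositions. Sites
#' extend them (or replace the name mappings) through [clif_vocabulary()].
#'
#' `location_category` distinguishes at least `icu`, `ward`, `ed`,
#' `procedural`, and `other`; ICU admissions are identified as ADT segments
#' with `location_category == "icu"`.
#'
#' @return Named list of [clif_vocabulary] objects, keyed by element name.
#' @export
clif_vocabularies <- function() {
  vocabs <- list(
    clif_vocabulary("vital_category", c(
      "temp_c", "temp_f", "heart_rate", "sbp", "dbp", "map",
      "spo2", "respiratory_rate", "weight_kg", "height_cm"
    )),
    clif_vocabulary("lab_category", c(
      "hemoglobin", "albumin", "ast", "alt", "creatinine", "bun",
      "sodium", "potassium", "chloride", "bicarbonate", "glucose",
      "wbc", "platelet_count", "lactate", "bilirubin_total"
    )),
    clif_vocabulary("location_category", c(
      "icu", "ward", "ed", "procedural", "stepdown", "other"
    )),
    clif_vocabulary("device_category", c(
      "imv", "nippv", "high_flow_nc", "nasal_cannula", "face_mask",
      "trach_collar", "room_air", "other"
    )),
    clif_vocabulary("mode_category", c(
      "assist_control_volume", "simv", "pressure_support",
      "pressure_control", "other"
    )),
    clif_vocabulary("med_category", c(
      "norepinephrine", "epinephrine", "vasopressin", "phenylephrine",
      "propofol", "fentanyl", "midazolam", "dexmedetomidine",
      "insulin", "heparin", "other"
    )),
    clif_vocabulary("score_category", c(
      "gcs_total", "rass", "cam_icu", "braden", "sofa_total"
    )),
    clif_vocabulary("sex_category", c("female", "male", "unknown")),
    clif_vocabulary("race_category", c("asian", "black", "white", "other")),
    clif_vocabulary("ethnicity_category", c("hispanic", "non_hispanic")),
    clif_vocabulary("discharge_category", c(
      "home", "snf", "rehab", "hospice", "ama", "expired", "other"
    ))
  )
  stats::setNames(vocabs, vapply(vocabs, function(v) v$element, character(1)))
}

# Look up the category for each source name under a vocabulary mapping;
# unmapped names yield NA. `_name` strings are matched after trimming and
# case-folding (deterministic matching), but are never themselves altered.
map_names_to_categories <- function(names, vocabulary) {
  if (length(vocabulary$mapping) == 0) {
    return(rep(NA_character_, length(names)))
  }
  lut <- stats::setNames(unname(vocabulary$mapping), norm_category(names(vocabulary$mapping)))
  unname(lut[norm_category(names)])
}

#' Populate a `_category` column from its `_name` column
#'
#' Applies a site-specific name-to-category mapping for one mCIDE element to a
#' CLIF table: rows whose `_name` value appears in the vocabulary mapping get
#' the mapped category; unmapped names are left `NA` and counted. The `_name`
#' values are never altered, preserving the source EHR labels for quality
#' control. The operation is idempotent.
#'
#' @param table A CLIF table (data frame) holding the element's `_name` column.
#' @param vocabulary A [clif_vocabulary] whose `element` matches a `_category`
#'   column of `table` (e.g. `lab_category` for the labs table).
#' @return The table with the `_category` column (re)populated. The attribute
#'   `"unmapped"` holds a list with the unmapped row count and the distinct
#'   unmapped names.
#' @export
apply_category_mapping <- function(table, vocabulary) {
  stopifnot(inherits(vocabulary, "clif_vocabulary"), is.data.frame(table))
  cat_col <- vocabulary$element
  name_col <- sub("_category$", "_name", cat_col)
  if (identical(name_col, cat_col)) {
    rlang::abort(sprintf("Vocabulary element '%s' is not a `_category` element.", cat_col))
  }
  if (!name_col %in% names(table)) {
    rlang::abort(sprintf(
      "Table has no '%s' column; vocabulary '%s' does not apply.", name_col, cat_col
    ))
  }
  if (nrow(table) == 0) {
    table[[cat_col]] <- character(0)
    attr(table, "unmapped") <- list(n = 0L, names = character(0))
    return(table)
  }
  mapped <- map_names_to_categories(table[[name_col]], vocabulary)
  table[[cat_col]] <- mapped
  unmapped_idx <- which(is.na(mapped) & !is.na(table[[name_col]]))
  attr(table, "unmapped") <- list(
    n = length(unmapped_idx),
    names = unique(as.character(table[[name_col]][unmapped_idx]))
  )
  table
}
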