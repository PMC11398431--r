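#' Reference temperature trajectories for subphenotype classification
#'
#' The four temperature-trajectory subphenotypes of critical illness are
#' normothermic (NT), hypothermic (HT), hyperthermic fast resolver (HFR) and
#' hyperthermic slow resolver (HSR). Classification assigns each encounter to
#' the reference curve with the lowest mean squared error over the first 72
#' hours of ICU admission.
#'
#' `reference_trajectories()` builds a `clif_reference_trajectories` object
#' from a data frame with columns `hour` (0..72, complete) and `NT`, `HT`,
#' `HFR`, `HSR` (degrees Celsius, no missing values), e.g. as read from a CSV
#' of externally supplied published curves.
#'
#' @param curves Data frame with columns `hour`, `NT`, `HT`, `HFR`, `HSR`.
#' @return An object of class `clif_reference_trajectories` (a tibble).
#' @export
reference_trajectories <- function(curves) {
  curves <- tibble::as_tibble(curves)
  needed <- c("hour", SUBPHENOTYPE_LEVELS)
  missing_cols <- setdiff(needed, names(curves))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Reference curves are missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  curves <- curves[, needed]
  curves <- curves[order(curves$hour), ]
  if (!identical(as.integer(curves$hour), 0:72)) {
    rlang::abort("Reference curves must cover exactly hours 0..72.")
  }
  if (anyNA(curves[SUBPHENOTYPE_LEVELS])) {
    rlang::abort("Reference curves must have no missing hourly values.")
  }
  class(curves) <- c("clif_reference_trajectories", class(curves))
  curves
}

# Fixed label order; also the tie-break order for classification.
SUBPHENOTYPE_LEVELS <- c("NT", "HT", "HFR", "HSR")

# Exponential-decay curve: plateau + (start - plateau) * 2^(-hour/half_life).
decay_curve <- function(hour, start, plateau, half_life) {
  if (is.infinite(half_life)) return(rep(start, length(hour)))
  plateau + (start - plateau) * 2^(-hour / half_life)
}

#' Default (synthetic) reference trajectories
#'
#' Builds four hourly curves over hours 0–72 with the qualitative shapes the
#' subphenotype labels imply: NT flat near 37.0 degC; HT starting near
#' 36.2 degC and remaining below NT throughout; HFR starting near 38.6 degC
#' and resolving to about 37.0 degC within roughly 24 h; HSR starting near
#' 38.6 degC and resolving slowly over the full 72 h.
#'
#' These are synthetic stand-ins parameterized by (start, plateau, resolution
#' half-life), NOT the published group-based-trajectory-model curves, which
#' are not publicly printed. For analyses against the published model, supply
#' its curves via [reference_trajectories()]; every classifier function
#' accepts an externally supplied set.
#'
#' @param params Optional named list overriding per-label curve parameters;
#'   each entry is `c(start =, plateau =, half_life =)`.
#' @return A `clif_reference_trajectories` object (73 hourly points per curve).
#' @examples
#' refs <- default_reference_trajectories()
#' head(refs)
#' @export
default_reference_trajectories <- function(params = NULL) {
  defaults <- list(
    NT  = c(start = 37.0, plateau = 37.0, half_life = Inf),
    HT  = c(start = 36.2, plateau = 36.5, half_life = 36),
    HFR = c(start = 38.6, plateau = 37.0, half_life = 6),
    HSR = c(start = 38.6, plateau = 37.0, half_life = 30)
  )
  if (!is.null(params)) {
    for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  }
  hour <- 0:72
  curves <- tibble::tibble(hour = hour)
  for (lab in SUBPHENOTYPE_LEVELS) {
    p <- defaults[[lab]]
    curves[[lab]] <- decay_curve(hour, p[["start"]], p[["plateau"]], p[["half_life"]])
  }
  reference_trajectories(curves)
}

#' Read / write reference trajectories as CSV
#'
#' The interchange format is a CSV with columns `hour, NT, HT, HFR, HSR`.
#'
#' @param path CSV path.
#' @return `read_reference_trajectories` returns a
#'   `clif_reference_trajectories`; `write_reference_trajectories` returns
#'   `path` invisibly.
#' @export
read_reference_trajectories <- function(path) {
  reference_trajectories(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_reference_trajectories
#' @param refset A `clif_reference_trajectories` object.
#' @export
write_reference_trajectories <- function(refset, path) {
  stopifnot(inherits(refset, "clif_reference_trajectories"))
  readr::write_csv(as.data.frame(refset), path)
  invisible(path)
}
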