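# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so no hidden global state leaks between operations.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + (string_hash(stream) %% 1000L)
}

# Polynomial rolling hash of a character scalar into [0, 2^31); all
# intermediates stay below 2^53 so double arithmetic is exact. Used for
# config fingerprints in run manifests and for seed stream derivation.
string_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 5381
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", string_hash(as.character(json)))
}

# Case-insensitive, whitespace-trimmed normalization used for all category
# comparisons (categories are stored lower_snake_case).
norm_category <- function(x) tolower(trimws(as.character(x)))

is_datetime <- function(x) inherits(x, "POSIXct")

as_utc <- function(x) {
  if (is_datetime(x)) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

hours <- function(h) h * 3600

# ISO-8601-ish datetime parsing to UTC; unparseable elements become NA
# instead of erroring, so the loader can report them.
parse_datetime_utc <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC", origin = "1970-01-01")
  remaining <- !is.na(x)
  for (f in formats) {
    if (!any(remaining)) break
    parsed <- as.POSIXct(strptime(x[remaining], format = f, tz = "UTC"))
    ok <- !is.na(parsed)
    out[which(remaining)[ok]] <- parsed[ok]
    remaining[remaining] <- !ok
  }
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  invisible(x)
}
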