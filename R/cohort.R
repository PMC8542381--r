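# Patient-level cohort data model and CSV plumbing.
#
# A cohort is an ordinary tibble with one row per hospitalized child and the
# canonical column dictionary below. Missing values are real NAs, never
# sentinel numerics; `died` must always be observed (studies without survival
# data are excluded upstream of this package).

COHORT_COLUMNS <- c(
  "patient_id", "age_months", "sex", "spo2", "chest_indrawing", "wheeze",
  "refusal_to_feed", "grunting", "cough_history", "unconscious",
  "illness_duration_days", "waz", "died"
)

COHORT_BOOL_COLUMNS <- c(
  "chest_indrawing", "wheeze", "refusal_to_feed", "grunting",
  "cough_history", "unconscious", "died"
)

COHORT_NUMERIC_COLUMNS <- c("age_months", "spo2", "illness_duration_days", "waz")

# Plausibility windows; out-of-range values are treated as recording errors
# and set to missing (with a warning) rather than propagated.
COHORT_RANGES <- list(
  age_months = c(0, Inf),
  spo2 = c(0, 100),
  illness_duration_days = c(0, Inf),
  waz = c(-10, 10)
)

TRUE_TOKENS <- c("1", "true", "yes", "t", "y")
FALSE_TOKENS <- c("0", "false", "no", "f", "n")

#' Build a patient cohort tibble
#'
#' Assembles and validates the canonical cohort table used by every function
#' in the package: one row per hospitalized child, with demographics, clinical
#' signs, the WHO weight-for-age z-score (WAZ) and the in-hospital survival
#' outcome. Any field other than `patient_id`, `age_months` and `died` may be
#' `NA` to represent a value not recorded at presentation.
#'
#' @param patient_id Character vector of unique record identifiers.
#' @param age_months Age at presentation, months (non-negative).
#' @param sex `"male"`/`"female"` (or `NA`).
#' @param spo2 Peripheral oxygen saturation by pulse oximetry, percent.
#' @param chest_indrawing,wheeze,refusal_to_feed,grunting,cough_history,unconscious
#'   Logical clinical signs (`NA` = not recorded). `cough_history` is history
#'   of cough, used in place of observed cough by the adapted PERCH score.
#' @param illness_duration_days Maximum reported duration of illness, days.
#' @param waz WHO weight-for-age z-score.
#' @param died Logical: hospitalized pneumonia-related death (never `NA`).
#' @return A tibble with the canonical cohort columns.
#' @examples
#' cohort(patient_id = "a", age_months = 12, sex = "female", spo2 = 88,
#'        chest_indrawing = TRUE, wheeze = FALSE, refusal_to_feed = FALSE,
#'        waz = -1.2, died = FALSE)
#' @export
cohort <- function(patient_id, age_months, sex = NA_character_, spo2 = NA_real_,
                   chest_indrawing = NA, wheeze = NA, refusal_to_feed = NA,
                   grunting = NA, cough_history = NA, unconscious = NA,
                   illness_duration_days = NA_real_, waz = NA_real_, died) {
  out <- tibble::tibble(
    patient_id = as.character(patient_id),
    age_months = as.numeric(age_months),
    sex = as.character(sex),
    spo2 = as.numeric(spo2),
    chest_indrawing = as.logical(chest_indrawing),
    wheeze = as.logical(wheeze),
    refusal_to_feed = as.logical(refusal_to_feed),
    grunting = as.logical(grunting),
    cough_history = as.logical(cough_history),
    unconscious = as.logical(unconscious),
    illness_duration_days = as.numeric(illness_duration_days),
    waz = as.numeric(waz),
    died = as.logical(died)
  )
  validate_cohort(out)
}

#' Validate a cohort tibble
#'
#' Checks the canonical column set and the field invariants (ages
#' non-negative, SpO2 within 0-100, WAZ within the plausibility window
#' -10..10, `died` and `age_months` never missing, sex tokens valid).
#' Returns the tibble invisibly unchanged so it can be piped.
#'
#' @param x A cohort tibble.
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(x$died)) abort("`died` must be observed for every record.")
  if (anyNA(x$age_months)) abort("`age_months` must be observed for every record.")
  if (any(x$age_months < 0)) abort("`age_months` must be non-negative.")
  bad_sex <- !is.na(x$sex) & !x$sex %in% c("male", "female")
  if (any(bad_sex)) abort("`sex` must be 'male', 'female' or NA.")
  rng <- COHORT_RANGES$spo2
  if (any(!is.na(x$spo2) & (x$spo2 < rng[1] | x$spo2 > rng[2]))) {
    abort("`spo2` must lie in [0, 100] when present.")
  }
  rng <- COHORT_RANGES$waz
  if (any(!is.na(x$waz) & (x$waz < rng[1] | x$waz > rng[2]))) {
    abort("`waz` must lie in the plausibility window [-10, 10] when present.")
  }
  invisible(x)
}

parse_bool_tokens <- function(x, true_tokens = TRUE_TOKENS,
                              false_tokens = FALSE_TOKENS) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% tolower(true_tokens)] <- TRUE
  out[tok %in% tolower(false_tokens)] <- FALSE
  unparseable <- !is.na(tok) & tok != "" & tok != "na" &
    !tok %in% tolower(c(true_tokens, false_tokens))
  list(value = out, n_bad = sum(unparseable))
}

parse_numeric_range <- function(x, range) {
  val <- suppressWarnings(as.numeric(x))
  raw <- trimws(as.character(x))
  bad_parse <- !is.na(raw) & raw != "" & tolower(raw) != "na" & is.na(val)
  out_of_range <- !is.na(val) & (val < range[1] | val > range[2])
  val[out_of_range] <- NA_real_
  list(value = val, n_bad = sum(bad_parse) + sum(out_of_range))
}

#' Read a cohort from CSV
#'
#' Reads a patient-level CSV into the canonical cohort tibble. Column names
#' may be remapped through a dialect (a named list or a YAML/JSON file path
#' with elements `columns`, a map from canonical name to the file's column
#' name, and optionally `true_tokens`/`false_tokens`). Booleans are parsed
#' from 1/0, true/false, yes/no (case-insensitive); unparseable or
#' out-of-range numeric cells become `NA` and are counted in a single warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Optional column-mapping configuration (named list, or path
#'   to a YAML or JSON file).
#' @return A cohort tibble. The number of cells coerced to `NA` is attached as
#'   attribute `"n_parse_warnings"`.
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  dialect <- load_dialect(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) abort(paste0("Cohort file is empty: ", path))

  colmap <- dialect$columns %||% setNames(as.list(COHORT_COLUMNS), COHORT_COLUMNS)
  for (canon in COHORT_COLUMNS) {
    src <- colmap[[canon]] %||% canon
    if (src %in% names(raw) && src != canon) names(raw)[names(raw) == src] <- canon
  }
  mandatory <- c("patient_id", "age_months", "died")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    abort(paste0("Cohort file lacks mandatory column(s): ",
                 paste(absent, collapse = ", ")))
  }
  for (canon in setdiff(COHORT_COLUMNS, names(raw))) raw[[canon]] <- NA_character_

  n_bad <- 0L
  out <- tibble::tibble(patient_id = as.character(raw$patient_id))
  for (col in COHORT_NUMERIC_COLUMNS) {
    parsed <- parse_numeric_range(raw[[col]], COHORT_RANGES[[col]])
    out[[col]] <- parsed$value
    n_bad <- n_bad + parsed$n_bad
  }
  sex_tok <- tolower(trimws(as.character(raw$sex)))
  sex <- rep(NA_character_, length(sex_tok))
  sex[sex_tok %in% c("male", "m")] <- "male"
  sex[sex_tok %in% c("female", "f")] <- "female"
  n_bad <- n_bad + sum(!is.na(sex_tok) & sex_tok != "" & sex_tok != "na" & is.na(sex))
  out$sex <- sex
  for (col in COHORT_BOOL_COLUMNS) {
    parsed <- parse_bool_tokens(raw[[col]],
                                dialect$true_tokens %||% TRUE_TOKENS,
                                dialect$false_tokens %||% FALSE_TOKENS)
    out[[col]] <- parsed$value
    n_bad <- n_bad + parsed$n_bad
  }
  if (anyNA(out$died)) {
    abort("`died` is missing or unparseable for some records; survival status is mandatory.")
  }
  if (n_bad > 0L) {
    warn(paste0(n_bad, " cell(s) were unparseable or out of range and were set to NA."))
  }
  out <- out[COHORT_COLUMNS]
  validate_cohort(out)
  attr(out, "n_parse_warnings") <- n_bad
  out
}

load_dialect <- function(dialect) {
  if (is.null(dialect)) return(list())
  if (is.character(dialect) && length(dialect) == 1L) {
    if (grepl("\\.json$", dialect, ignore.case = TRUE)) {
      return(jsonlite::read_json(dialect, simplifyVector = FALSE))
    }
    return(yaml::read_yaml(dialect))
  }
  if (!is.list(dialect)) abort("`dialect` must be a named list or a file path.")
  dialect
}

#' Write a cohort to CSV
#'
#' Serializes a cohort tibble in the canonical column dictionary: UTF-8 CSV,
#' booleans as 1/0, missing values as empty cells. `read_cohort()` applied to
#' the output reproduces the input field-for-field.
#'
#' @param x A cohort tibble (non-empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  if (nrow(x) == 0L) abort("Refusing to write an empty cohort.")
  out <- x[COHORT_COLUMNS]
  for (col in COHORT_BOOL_COLUMNS) out[[col]] <- as.integer(out[[col]])
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
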