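# Score specifications and the complete-case, age-window eligibility filter.

#' Score specification
#'
#' Describes one of the three supported risk scores: its half-open age window
#' in months and the cohort fields it requires. The default windows follow the
#' validation cohorts in which each score is applied: RISC for HIV-negative
#' children 0-24 months (`[0, 25)` under the completed-month convention),
#' RISC-Malawi 2-59 months (`[2, 60)`), adapted PERCH 1-59 months
#' (`[1, 60)`). The RISC score can also be applied to children 0-59 months as
#' a supplementary analysis via `risc_age_window = c(0, 60)`.
#'
#' @param score_name One of `"risc_hiv_negative"`, `"risc_malawi_waz"`,
#'   `"perch_adapted"`.
#' @param risc_age_window Length-2 numeric, the `[lo, hi)` age window in
#'   months for the RISC score; must be `c(0, 25)` (default) or `c(0, 60)`.
#' @param perch_unresponsive_weight Points contributed by unconsciousness in
#'   the adapted PERCH score; 0 (default, matching the published external
#'   maximum of 12) or 2 (the original "unresponsive without deep breathing"
#'   weight, for sensitivity analyses).
#' @return A list of class `score_spec` with elements `score_name`,
#'   `age_window` (`[lo, hi)` months), `required_fields`, and `config`.
#' @examples
#' score_spec("risc_malawi_waz")
#' @export
score_spec <- function(score_name,
                       risc_age_window = c(0, 25),
                       perch_unresponsive_weight = 0) {
  score_name <- match_score_name(score_name)
  if (!perch_unresponsive_weight %in% c(0, 2)) {
    abort("`perch_unresponsive_weight` must be 0 or 2.")
  }
  if (score_name == "risc_hiv_negative") {
    if (!(identical(as.numeric(risc_age_window), c(0, 25)) ||
          identical(as.numeric(risc_age_window), c(0, 60)))) {
      abort("`risc_age_window` must be c(0, 25) or c(0, 60).")
    }
  }
  window <- switch(score_name,
    risc_hiv_negative = as.numeric(risc_age_window),
    risc_malawi_waz = c(2, 60),
    perch_adapted = c(1, 60)
  )
  required <- switch(score_name,
    risc_hiv_negative = c("spo2", "chest_indrawing", "wheeze",
                          "refusal_to_feed", "waz"),
    risc_malawi_waz = c("spo2", "sex", "wheeze", "unconscious", "waz"),
    perch_adapted = c("age_months", "sex", "cough_history", "grunting",
                      "spo2", "illness_duration_days", "waz", "unconscious")
  )
  structure(
    list(score_name = score_name, age_window = window,
         required_fields = required,
         config = list(perch_unresponsive_weight = perch_unresponsive_weight)),
    class = "score_spec"
  )
}

as_score_spec <- function(x, ...) {
  if (inherits(x, "score_spec")) x else score_spec(x, ...)
}

#' @export
print.score_spec <- function(x, ...) {
  cat("<score_spec> ", x$score_name, "\n",
      "  age window [", x$age_window[1], ", ", x$age_window[2], ") months\n",
      "  required fields: ", paste(x$required_fields, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Complete-case, age-window eligibility filter
#'
#' Reproduces the complete-case analysis applied before scoring: a child is
#' eligible for a score if and only if their age falls in the score's
#' half-open age window *and* every field the score requires is observed.
#' Age is assessed first, so a record failing both conditions is tallied as an
#' age exclusion. The counts always satisfy
#' `n_input = n_eligible + n_excluded_age + n_excluded_missing`.
#'
#' @param x A cohort tibble.
#' @param spec A `score_spec` or a score name string.
#' @param ... Passed to [score_spec()] when `spec` is a name.
#' @return A list with elements
#'   \describe{
#'     \item{eligible}{the eligible sub-cohort (tibble),}
#'     \item{report}{a one-row tibble with `score_name`, `n_input`,
#'       `n_eligible`, `n_excluded_age`, `n_excluded_missing`,}
#'     \item{reasons}{a tibble (`patient_id`, `reason`) for excluded records,
#'       `reason` either `"age"` or `"missing:<field,...>"`.}
#'   }
#' @examples
#' co <- cohort(patient_id = c("a", "b"), age_months = c(12, 30),
#'              spo2 = c(92, 95), chest_indrawing = c(TRUE, FALSE),
#'              wheeze = FALSE, refusal_to_feed = FALSE, waz = c(-1, 0),
#'              died = FALSE)
#' filter_eligible(co, "risc_hiv_negative")$report
#' @export
filter_eligible <- function(x, spec, ...) {
  validate_cohort(x)
  spec <- as_score_spec(spec, ...)
  if (nrow(x) == 0L) {
    return(list(
      eligible = x,
      report = tibble::tibble(score_name = spec$score_name, n_input = 0L,
                              n_eligible = 0L, n_excluded_age = 0L,
                              n_excluded_missing = 0L),
      reasons = tibble::tibble(patient_id = character(), reason = character())
    ))
  }
  in_age <- x$age_months >= spec$age_window[1] & x$age_months < spec$age_window[2]
  req <- as.matrix(is.na(x[spec$required_fields]))
  complete <- !apply(req, 1L, any)
  eligible <- in_age & complete

  reason <- rep(NA_character_, nrow(x))
  reason[!in_age] <- "age"
  miss_rows <- which(in_age & !complete)
  if (length(miss_rows)) {
    reason[miss_rows] <- vapply(miss_rows, function(i) {
      paste0("missing:", paste(spec$required_fields[req[i, ]], collapse = ","))
    }, character(1))
  }

  list(
    eligible = x[eligible, , drop = FALSE],
    report = tibble::tibble(
      score_name = spec$score_name,
      n_input = nrow(x),
      n_eligible = sum(eligible),
      n_excluded_age = sum(!in_age),
      n_excluded_missing = sum(in_age & !complete)
    ),
    reasons = tibble::tibble(patient_id = x$patient_id[!eligible],
                             reason = reason[!eligible])
  )
}
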