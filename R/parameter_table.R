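# Per-parameter cohort summaries: for each stratum of a score, the number of
# children presenting with that sign, the share of the cohort, deaths, and
# the case-fatality ratio with exact confidence interval. Strata are not
# mutually exclusive: a child contributes to every row whose condition it
# meets.

score_strata <- function(score_name) {
  switch(score_name,
    risc_hiv_negative = list(
      "SpO2 <= 90%" = function(x) x$spo2 <= 90,
      "Chest indrawing (with SpO2 > 90%)" = function(x) x$chest_indrawing & x$spo2 > 90,
      "Wheezing" = function(x) x$wheeze,
      "Refusal to feed" = function(x) x$refusal_to_feed,
      "WAZ <= -3" = function(x) categorize_waz(x$waz, "risc") == "severe",
      "WAZ > -3 to <= -2" = function(x) categorize_waz(x$waz, "risc") == "moderate"
    ),
    risc_malawi_waz = list(
      "SpO2 >= 93%" = function(x) x$spo2 >= 93,
      "SpO2 90%-92%" = function(x) x$spo2 >= 90 & x$spo2 < 93,
      "SpO2 < 90%" = function(x) x$spo2 < 90,
      "WAZ > -2" = function(x) categorize_waz(x$waz, "risc_malawi") == "normal",
      "WAZ -3 to < -2" = function(x) categorize_waz(x$waz, "risc_malawi") == "moderate",
      "WAZ < -3" = function(x) categorize_waz(x$waz, "risc_malawi") == "severe",
      "Female" = function(x) x$sex == "female",
      "Wheezing" = function(x) x$wheeze,
      "Unconscious" = function(x) x$unconscious
    ),
    perch_adapted = list(
      "Age 1-11 months" = function(x) x$age_months < 12,
      "Female" = function(x) x$sex == "female",
      "Unresponsiveness" = function(x) x$unconscious,
      "Cough (history)" = function(x) x$cough_history,
      "Grunting (observed)" = function(x) x$grunting,
      "SpO2 < 92%" = function(x) x$spo2 < 92,
      "Duration of illness >= 3 d" = function(x) x$illness_duration_days >= 3,
      "WAZ < -3" = function(x) categorize_waz(x$waz, "perch") == "severe",
      "WAZ >= -3 to < -2" = function(x) categorize_waz(x$waz, "perch") == "moderate"
    )
  )
}

#' Per-parameter summary table for a score
#'
#' For an eligible (complete-case) cohort, tabulates each parameter stratum
#' of the score: how many children present with the sign, the percentage of
#' the cohort, the number of deaths among them, and the stratum
#' case-fatality ratio with a Clopper-Pearson interval, plus a Total row for
#' the whole cohort. Strata overlap by design (a hypoxemic child with severe
#' underweight appears in both rows).
#'
#' @param x An eligible cohort tibble (non-empty, complete in the score's
#'   required fields).
#' @param spec A `score_spec` or score name string.
#' @param level Confidence level.
#' @param ... Passed to [score_spec()] when `spec` is a name.
#' @return A tibble: `parameter`, `n`, `pct` (share of cohort, percent),
#'   `deaths`, `cfr_pct`, `cfr_low`, `cfr_high` (percent scale).
#' @export
build_parameter_table <- function(x, spec, level = 0.95, ...) {
  spec <- as_score_spec(spec, ...)
  if (nrow(x) == 0L) abort("Cannot summarize an empty cohort.")
  check_required_present(x, spec$required_fields, spec$score_name)
  strata <- score_strata(spec$score_name)
  n_total <- nrow(x)
  rows <- purrr::imap(strata, function(pred, label) {
    hit <- pred(x)
    n <- sum(hit)
    deaths <- sum(x$died & hit)
    ci <- if (n > 0) exact_binomial_ci(deaths, n, level) else NULL
    tibble::tibble(
      parameter = label, n = n, pct = 100 * n / n_total, deaths = deaths,
      cfr_pct = if (n > 0) 100 * ci$estimate else NA_real_,
      cfr_low = if (n > 0) 100 * ci$ci_low else NA_real_,
      cfr_high = if (n > 0) 100 * ci$ci_high else NA_real_
    )
  })
  total_ci <- exact_binomial_ci(sum(x$died), n_total, level)
  total_row <- tibble::tibble(
    parameter = "Total", n = n_total, pct = 100, deaths = sum(x$died),
    cfr_pct = 100 * total_ci$estimate, cfr_low = 100 * total_ci$ci_low,
    cfr_high = 100 * total_ci$ci_high
  )
  dplyr::bind_rows(c(unname(rows), list(total_row)))
}
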