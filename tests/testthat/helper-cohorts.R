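# Shared fixture builders. Everything is generated in code; no stored data.

# A fully observed record with sensible defaults, overridable per field.
complete_record <- function(id = "r1", ...) {
  defaults <- list(
    patient_id = id, age_months = 12, sex = "male", spo2 = 95,
    chest_indrawing = FALSE, wheeze = FALSE, refusal_to_feed = FALSE,
    grunting = FALSE, cough_history = TRUE, unconscious = FALSE,
    illness_duration_days = 2, waz = 0, died = FALSE
  )
  do.call(cohort, utils::modifyList(defaults, list(...)))
}

# A complete random cohort with n rows (all fields observed).
random_complete_cohort <- function(n, p_death = 0.2) {
  cohort(
    patient_id = sprintf("rc%04d", seq_len(n)),
    age_months = runif(n, 0, 60),
    sex = sample(c("male", "female"), n, replace = TRUE),
    spo2 = runif(n, 70, 100),
    chest_indrawing = runif(n) < 0.5,
    wheeze = runif(n) < 0.3,
    refusal_to_feed = runif(n) < 0.15,
    grunting = runif(n) < 0.2,
    cough_history = runif(n) < 0.9,
    unconscious = runif(n) < 0.05,
    illness_duration_days = runif(n, 0, 14),
    waz = runif(n, -4.5, 1),
    died = runif(n) < p_death
  )
}

# Random integer scores + outcomes with both classes guaranteed.
random_scored <- function(n, score_range = c(-2, 10), p_death = 0.3) {
  repeat {
    d <- tibble::tibble(
      total = sample(seq(score_range[1], score_range[2]), n, replace = TRUE),
      died = runif(n) < p_death
    )
    if (sum(d$died) >= 1 && sum(!d$died) >= 1) return(d)
  }
}
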