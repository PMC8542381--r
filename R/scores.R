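# The three weighted point scores, exactly as published, with per-parameter
# contribution breakdowns and exhaustive score-range enumeration.
#
# Weight tables:
#   RISC (HIV-negative, 0-24 mo): SpO2<=90% -> 3; otherwise chest indrawing
#     -> 2; wheeze -> -2; refusal to feed -> +1; WAZ<=-3 -> 2; -3<WAZ<=-2 -> 1.
#   RISC-Malawi (WAZ variant, 2-59 mo): SpO2>=93 -> 0, 90-92 -> 1, <90 -> 5;
#     WAZ>=-2 -> 0, -3<=WAZ<-2 -> 3, WAZ<-3 -> 6; female -> 1; wheeze -> -1;
#     unconscious -> 5.
#   Adapted PERCH (1-59 mo): age<12 mo -> 2; female -> 1; history of cough
#     -> -1; grunting -> 2; SpO2<92 -> 2; illness 3-5 d -> 2, >5 d -> 2;
#     WAZ<-3 -> 3, -3<=WAZ<-2 -> 2; unconsciousness -> configurable (0 or 2).

#' Categorize a weight-for-age z-score
#'
#' Maps a WAZ value to the malnutrition band used by a score. The two scores
#' published slightly different boundary conventions: the RISC score places
#' exactly -3 in the severe band (`waz <= -3` severe, `-3 < waz <= -2`
#' moderate), whereas RISC-Malawi and the adapted PERCH score place it in the
#' moderate band (`waz < -3` severe, `-3 <= waz < -2` moderate, `waz >= -2`
#' normal). Every finite WAZ maps to exactly one band under either convention.
#'
#' @param waz Numeric vector of weight-for-age z-scores (no `NA`s).
#' @param convention `"risc"`, `"risc_malawi"`, or `"perch"` (the latter two
#'   share the same rule).
#' @return Factor with levels `severe`, `moderate`, `normal`.
#' @examples
#' categorize_waz(-3, "risc")        # severe
#' categorize_waz(-3, "risc_malawi") # moderate
#' @export
categorize_waz <- function(waz, convention = c("risc", "risc_malawi", "perch")) {
  convention <- match.arg(convention)
  if (anyNA(waz)) abort("`waz` contains missing values; filter the cohort first.")
  if (any(!is.finite(waz))) abort("`waz` must be finite.")
  out <- if (convention == "risc") {
    ifelse(waz <= -3, "severe", ifelse(waz <= -2, "moderate", "normal"))
  } else {
    ifelse(waz < -3, "severe", ifelse(waz < -2, "moderate", "normal"))
  }
  factor(out, levels = c("severe", "moderate", "normal"))
}

check_required_present <- function(x, fields, score_name) {
  for (f in fields) {
    if (anyNA(x[[f]])) {
      abort(paste0("`", f, "` is missing for ", sum(is.na(x[[f]])),
                   " record(s); ", score_name,
                   " requires it. Apply filter_eligible() first."))
    }
  }
}

#' Score a cohort with the RISC score for HIV-negative children
#'
#' Applies the RISC weights, including the conditional rule that chest
#' indrawing only enters the score when SpO2 exceeds 90% (when SpO2 is at or
#' below 90% the 3-point hypoxemia term replaces it). The returned tibble
#' carries one `pts_*` column per parameter; their row sums equal `total`.
#'
#' @param x A cohort tibble with no missing values in the RISC fields
#'   (`spo2`, `chest_indrawing`, `wheeze`, `refusal_to_feed`, `waz`).
#' @return A tibble: `patient_id`, `score_name`, `pts_spo2`,
#'   `pts_chest_indrawing`, `pts_wheeze`, `pts_refusal_to_feed`, `pts_waz`,
#'   `total`, `died`.
#' @examples
#' co <- cohort(patient_id = "a", age_months = 6, spo2 = 85,
#'              chest_indrawing = TRUE, wheeze = FALSE,
#'              refusal_to_feed = TRUE, waz = -3.5, died = FALSE)
#' score_risc_hiv_negative(co)$total  # 6
#' @export
score_risc_hiv_negative <- function(x) {
  fields <- score_spec("risc_hiv_negative")$required_fields
  check_required_present(x, fields, "risc_hiv_negative")
  hypox <- x$spo2 <= 90
  waz_cat <- categorize_waz(x$waz, "risc")
  out <- tibble::tibble(
    patient_id = x$patient_id,
    score_name = "risc_hiv_negative",
    pts_spo2 = ifelse(hypox, 3L, 0L),
    pts_chest_indrawing = ifelse(!hypox & x$chest_indrawing, 2L, 0L),
    pts_wheeze = ifelse(x$wheeze, -2L, 0L),
    pts_refusal_to_feed = ifelse(x$refusal_to_feed, 1L, 0L),
    pts_waz = c(severe = 2L, moderate = 1L, normal = 0L)[as.character(waz_cat)]
  )
  finish_score(out, x)
}

#' Score a cohort with the RISC-Malawi score (weight-for-age variant)
#'
#' Applies the RISC-Malawi weights with WAZ as the nutritional parameter.
#' SpO2 bands are evaluated on the raw recorded percent on the real line:
#' `[93, Inf)` scores 0, `[90, 93)` scores 1, `(-Inf, 90)` scores 5.
#'
#' @param x A cohort tibble with no missing values in the RISC-Malawi fields
#'   (`spo2`, `sex`, `wheeze`, `unconscious`, `waz`).
#' @return A tibble with `pts_*` component columns, `total`, `died`.
#' @examples
#' co <- cohort(patient_id = "a", age_months = 24, sex = "female", spo2 = 88,
#'              wheeze = FALSE, unconscious = TRUE, waz = -3.2, died = FALSE)
#' score_risc_malawi_waz(co)$total  # 17
#' @export
score_risc_malawi_waz <- function(x) {
  fields <- score_spec("risc_malawi_waz")$required_fields
  check_required_present(x, fields, "risc_malawi_waz")
  waz_cat <- categorize_waz(x$waz, "risc_malawi")
  out <- tibble::tibble(
    patient_id = x$patient_id,
    score_name = "risc_malawi_waz",
    pts_spo2 = ifelse(x$spo2 >= 93, 0L, ifelse(x$spo2 >= 90, 1L, 5L)),
    pts_waz = c(severe = 6L, moderate = 3L, normal = 0L)[as.character(waz_cat)],
    pts_sex = ifelse(x$sex == "female", 1L, 0L),
    pts_wheeze = ifelse(x$wheeze, -1L, 0L),
    pts_unconscious = ifelse(x$unconscious, 5L, 0L)
  )
  finish_score(out, x)
}

#' Score a cohort with the adapted PERCH score
#'
#' Applies the PERCH weights as adapted for data sets lacking the "deep
#' breathing" variable: history of cough replaces observed cough,
#' unconsciousness replaces unresponsiveness, and WAZ replaces
#' weight-for-height. With the default `unresponsive_weight = 0` the
#' achievable range is -1 to 12, the published external-application maximum;
#' setting it to 2 restores the original "unresponsive without deep
#' breathing" weight for sensitivity analyses. The two illness-duration
#' categories (3-5 days, more than 5 days) carry equal weight but are kept
#' distinct in the `duration_band` column.
#'
#' @param x A cohort tibble with no missing values in the adapted PERCH
#'   fields.
#' @param unresponsive_weight 0 (default) or 2.
#' @return A tibble with `pts_*` component columns, `duration_band`, `total`,
#'   `died`.
#' @examples
#' co <- cohort(patient_id = "a", age_months = 6, sex = "female", spo2 = 90,
#'              cough_history = FALSE, grunting = TRUE, unconscious = FALSE,
#'              illness_duration_days = 6, waz = -3.5, died = FALSE)
#' score_perch_adapted(co)$total  # 12
#' @export
score_perch_adapted <- function(x, unresponsive_weight = 0) {
  if (!unresponsive_weight %in% c(0, 2)) {
    abort("`unresponsive_weight` must be 0 or 2.")
  }
  fields <- score_spec("perch_adapted")$required_fields
  check_required_present(x, fields, "perch_adapted")
  waz_cat <- categorize_waz(x$waz, "perch")
  dur <- x$illness_duration_days
  duration_band <- factor(
    ifelse(dur < 3, "<3 d", ifelse(dur <= 5, "3-5 d", ">5 d")),
    levels = c("<3 d", "3-5 d", ">5 d")
  )
  out <- tibble::tibble(
    patient_id = x$patient_id,
    score_name = "perch_adapted",
    pts_age = ifelse(x$age_months < 12, 2L, 0L),
    pts_sex = ifelse(x$sex == "female", 1L, 0L),
    pts_cough_history = ifelse(x$cough_history, -1L, 0L),
    pts_grunting = ifelse(x$grunting, 2L, 0L),
    pts_spo2 = ifelse(x$spo2 < 92, 2L, 0L),
    pts_duration = ifelse(duration_band == "<3 d", 0L, 2L),
    pts_waz = c(severe = 3L, moderate = 2L, normal = 0L)[as.character(waz_cat)],
    pts_unconscious = ifelse(x$unconscious, as.integer(unresponsive_weight), 0L),
    duration_band = duration_band
  )
  finish_score(out, x)
}

finish_score <- function(out, x) {
  pts_cols <- grep("^pts_", names(out), value = TRUE)
  out$total <- as.integer(rowSums(out[pts_cols]))
  out$died <- x$died
  out
}

#' Score a cohort
#'
#' Dispatches to the scoring function named by `spec` and returns the scored
#' tibble. The cohort must already be eligible (complete in the score's
#' required fields); see [filter_eligible()].
#'
#' @param x A cohort tibble.
#' @param spec A `score_spec` or score name string.
#' @param ... Passed to [score_spec()] when `spec` is a name.
#' @return The scored tibble (see the individual scoring functions).
#' @export
score_cohort <- function(x, spec, ...) {
  spec <- as_score_spec(spec, ...)
  switch(spec$score_name,
    risc_hiv_negative = score_risc_hiv_negative(x),
    risc_malawi_waz = score_risc_malawi_waz(x),
    perch_adapted = score_perch_adapted(
      x, unresponsive_weight = spec$config$perch_unresponsive_weight)
  )
}

#' Enumerate the achievable range of a score
#'
#' Computes the minimum and maximum achievable totals by exhaustively scoring
#' one synthetic record per combination of parameter categories (respecting
#' the RISC conditional SpO2/chest-indrawing rule), never by reading the
#' published range. Representative in-band values are used for the continuous
#' inputs; every category of every parameter is covered.
#'
#' @param spec A `score_spec` or score name string.
#' @param ... Passed to [score_spec()] when `spec` is a name.
#' @return A named integer vector `c(min = ..., max = ...)`.
#' @examples
#' score_range("risc_hiv_negative")  # c(min = -2, max = 6)
#' @export
score_range <- function(spec, ...) {
  spec <- as_score_spec(spec, ...)
  grid <- switch(spec$score_name,
    risc_hiv_negative = expand.grid(
      spo2 = c(85, 95), chest_indrawing = c(TRUE, FALSE),
      wheeze = c(TRUE, FALSE), refusal_to_feed = c(TRUE, FALSE),
      waz = c(-3, -2.5, 0),   # -3 is severe under the RISC convention
      stringsAsFactors = FALSE
    ),
    risc_malawi_waz = expand.grid(
      spo2 = c(88, 91, 95), waz = c(-3.5, -2.5, 0),
      sex = c("male", "female"), wheeze = c(TRUE, FALSE),
      unconscious = c(TRUE, FALSE), stringsAsFactors = FALSE
    ),
    perch_adapted = expand.grid(
      age_months = c(6, 24), sex = c("male", "female"),
      cough_history = c(TRUE, FALSE), grunting = c(TRUE, FALSE),
      spo2 = c(90, 95), illness_duration_days = c(1, 4, 7),
      waz = c(-3.5, -2.5, 0), unconscious = c(TRUE, FALSE),
      stringsAsFactors = FALSE
    )
  )
  defaults <- list(age_months = 12, sex = "male", spo2 = 95,
                   chest_indrawing = FALSE, wheeze = FALSE,
                   refusal_to_feed = FALSE, grunting = FALSE,
                   cough_history = FALSE, unconscious = FALSE,
                   illness_duration_days = 1, waz = 0)
  rec <- tibble::as_tibble(grid)
  for (f in setdiff(names(defaults), names(rec))) rec[[f]] <- defaults[[f]]
  rec$patient_id <- sprintf("enum%05d", seq_len(nrow(rec)))
  rec$died <- FALSE
  co <- do.call(cohort, rec[c("patient_id", names(defaults), "died")])
  totals <- score_cohort(co, spec)$total
  c(min = min(totals), max = max(totals))
}
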