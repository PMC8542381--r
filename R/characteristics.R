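# Case-fatality ratios, exact binomial intervals, 2x2 tables and cut-point
# test characteristics.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (Clopper-Pearson) confidence bounds for a binomial proportion via
#' the beta-quantile closed form. The interval is conservative: realized
#' coverage is at least the nominal level. The lower bound is exactly 0 when
#' the numerator is 0 and the upper bound exactly 1 when the numerator equals
#' the denominator.
#'
#' @param x Number of events (vectorized).
#' @param n Number of trials (vectorized, `>= 1`).
#' @param level Confidence level, default 0.95.
#' @return A tibble: `x`, `n`, `estimate`, `ci_low`, `ci_high`, `level`
#'   (all proportions on the 0-1 scale).
#' @examples
#' exact_binomial_ci(20, 917)   # estimate 0.0218, CI (0.013, 0.033)
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (any(n < 1)) abort("`n` must be at least 1.")
  if (any(x < 0 | x > n)) abort("`x` must satisfy 0 <= x <= n.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  alpha <- 1 - level
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(x = as.integer(x), n = as.integer(n), estimate = x / n,
                 ci_low = lo, ci_high = hi, level = level)
}

#' Case-fatality ratio of a cohort
#'
#' The case-fatality ratio (CFR) is the number of deaths divided by the
#' number of patients, with a Clopper-Pearson exact confidence interval.
#'
#' @param x A cohort or scored tibble with a logical `died` column, or a
#'   logical vector of outcomes.
#' @param level Confidence level.
#' @return A one-row tibble as from [exact_binomial_ci()].
#' @examples
#' case_fatality_ratio(c(rep(TRUE, 61), rep(FALSE, 3513)))  # 1.7% (1.3-2.2)
#' @export
case_fatality_ratio <- function(x, level = 0.95) {
  died <- if (is.data.frame(x)) x$died else x
  if (length(died) == 0L) abort("Cannot compute a CFR on an empty cohort.")
  if (anyNA(died)) abort("`died` must be observed for every record.")
  exact_binomial_ci(sum(died), length(died), level = level)
}

#' Two-by-two classification table at a cut-point
#'
#' Classifies each child as high risk when their score is at or above the
#' cut-point (the `>=` rule) and cross-tabulates against death.
#'
#' @param data A tibble with integer `total` (score) and logical `died`
#'   columns, e.g. from [score_cohort()].
#' @param cutpoint Integer score threshold.
#' @return A one-row tibble: `cutpoint`, `tp`, `fp`, `fn`, `tn`.
#' @examples
#' d <- tibble::tibble(total = c(3, 4, 1, 2, 3),
#'                     died = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' two_by_two(d, 3)  # tp 2, fp 1, fn 0, tn 2
#' @export
two_by_two <- function(data, cutpoint) {
  positive <- data$total >= cutpoint
  tibble::tibble(
    cutpoint = cutpoint,
    tp = sum(positive & data$died),
    fp = sum(positive & !data$died),
    fn = sum(!positive & data$died),
    tn = sum(!positive & !data$died)
  )
}

#' Test characteristics of a two-by-two table
#'
#' Sensitivity, specificity (with Clopper-Pearson exact intervals), positive
#' and negative likelihood ratios (with log-method intervals), and the
#' percentage of all children correctly classified (true positives plus true
#' negatives over the total).
#'
#' Likelihood-ratio intervals use the standard log-variance method,
#' `SE(ln LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` (and the
#' symmetric formula for LR-), exponentiating normal bounds. A zero cell
#' makes an LR infinite or undefined; such values are reported as `Inf` /
#' `NaN` with `NA` bounds rather than raising an error, unless
#' `haldane = TRUE`, which adds 0.5 to every cell for the LR computations.
#'
#' @param table A one-row tibble from [two_by_two()] (or any list with
#'   `tp`, `fp`, `fn`, `tn`).
#' @param level Confidence level.
#' @param haldane Apply the Haldane 0.5 continuity correction to the LRs.
#' @return A one-row tibble with sensitivity/specificity estimates and CIs,
#'   `lr_pos`, `lr_neg` with CIs, and `correctly_classified_pct`.
#' @export
characteristics <- function(table, level = 0.95, haldane = FALSE) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  if (tp + fn < 1) abort("No deaths in the data; sensitivity is undefined.")
  if (fp + tn < 1) abort("No survivors in the data; specificity is undefined.")
  sens <- exact_binomial_ci(tp, tp + fn, level)
  spec <- exact_binomial_ci(tn, fp + tn, level)

  z <- qnorm(1 - (1 - level) / 2)
  if (haldane) {
    tp2 <- tp + 0.5; fp2 <- fp + 0.5; fn2 <- fn + 0.5; tn2 <- tn + 0.5
  } else {
    tp2 <- tp; fp2 <- fp; fn2 <- fn; tn2 <- tn
  }
  se2 <- tp2 / (tp2 + fn2); sp2 <- tn2 / (fp2 + tn2)
  lr_pos <- se2 / (1 - sp2)
  lr_neg <- (1 - se2) / sp2
  se_log_pos <- sqrt(1 / tp2 - 1 / (tp2 + fn2) + 1 / fp2 - 1 / (fp2 + tn2))
  se_log_neg <- sqrt(1 / fn2 - 1 / (tp2 + fn2) + 1 / tn2 - 1 / (fp2 + tn2))
  lr_ci <- function(lr, se_log) {
    if (!is.finite(lr) || lr == 0 || !is.finite(se_log)) return(c(NA_real_, NA_real_))
    exp(log(lr) + c(-1, 1) * z * se_log)
  }
  pos_ci <- lr_ci(lr_pos, se_log_pos)
  neg_ci <- lr_ci(lr_neg, se_log_neg)

  tibble::tibble(
    cutpoint = table$cutpoint %||% NA_integer_,
    sensitivity = sens$estimate, sens_low = sens$ci_low, sens_high = sens$ci_high,
    specificity = spec$estimate, spec_low = spec$ci_low, spec_high = spec$ci_high,
    lr_pos = lr_pos, lr_pos_low = pos_ci[1], lr_pos_high = pos_ci[2],
    lr_neg = lr_neg, lr_neg_low = neg_ci[1], lr_neg_high = neg_ci[2],
    correctly_classified_pct = 100 * (tp + tn) / (tp + fp + fn + tn)
  )
}

#' Sweep every cut-point of a score
#'
#' Builds the full cut-point table for a scored cohort: one row per integer
#' cut-point over the score's enumerated achievable range (or, when no score
#' name is supplied, the observed range), each row giving the CFR among
#' children with that exact score, the 2x2 counts at the `>=` rule, and the
#' test characteristics from [characteristics()]. Sensitivity is
#' non-increasing and specificity non-decreasing in the cut-point.
#'
#' @param data Tibble with `total` and `died` (e.g. [score_cohort()] output);
#'   both outcome classes must be present.
#' @param spec Optional `score_spec` or score name; fixes the cut-point range
#'   to the score's enumerated range.
#' @param level Confidence level.
#' @param haldane Passed to [characteristics()].
#' @return A tibble of class `cutpoint_table`, one row per cut-point, with
#'   `n_at`, `deaths_at`, `cfr_at_pct` and CI (the CFR among children whose
#'   score equals the cut-point, as a percentage; `NA` when no child has that
#'   score), the 2x2 counts, and the characteristics columns.
#' @export
cutpoint_sweep <- function(data, spec = NULL, level = 0.95, haldane = FALSE) {
  if (sum(data$died) < 1 || sum(!data$died) < 1) {
    abort("Both outcome classes must be present for a cut-point sweep.")
  }
  rng <- if (is.null(spec)) {
    c(min = min(data$total), max = max(data$total))
  } else {
    score_range(spec)
  }
  cuts <- seq.int(rng[["min"]], rng[["max"]])
  rows <- purrr::map(cuts, function(k) {
    at <- data$total == k
    n_at <- sum(at)
    cfr <- if (n_at > 0) exact_binomial_ci(sum(data$died & at), n_at, level)
           else NULL
    tab <- two_by_two(data, k)
    ch <- characteristics(tab, level = level, haldane = haldane)
    dplyr::bind_cols(
      tab,
      tibble::tibble(
        n_at = n_at,
        deaths_at = sum(data$died & at),
        cfr_at_pct = if (n_at > 0) 100 * cfr$estimate else NA_real_,
        cfr_at_low = if (n_at > 0) 100 * cfr$ci_low else NA_real_,
        cfr_at_high = if (n_at > 0) 100 * cfr$ci_high else NA_real_
      ),
      ch[setdiff(names(ch), "cutpoint")]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cutpoint_table", class(out))
  out
}

#' Recommend cut-points by the sensitivity/specificity rule
#'
#' Returns the cut-points whose sensitivity lies in a target band with a
#' concurrent specificity floor — by default sensitivity 60%-80% (inclusive)
#' with specificity at least 40%, the rule used to flag clinically usable
#' thresholds that identify low-risk children without sacrificing too much
#' specificity.
#'
#' @param table A `cutpoint_table` from [cutpoint_sweep()].
#' @param sens_range Inclusive sensitivity band, default `c(0.60, 0.80)`.
#' @param min_spec Inclusive specificity floor, default 0.40.
#' @return Integer vector of recommended cut-points, ascending (possibly
#'   empty).
#' @export
recommend_cutpoints <- function(table, sens_range = c(0.60, 0.80),
                                min_spec = 0.40) {
  if (nrow(table) == 0L) abort("`table` is empty.")
  keep <- table$sensitivity >= sens_range[1] & table$sensitivity <= sens_range[2] &
    table$specificity >= min_spec
  sort(table$cutpoint[keep])
}
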