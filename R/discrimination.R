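# ROC curves, AUC with confidence interval, qualitative discrimination
# bands, and risk predictiveness curves.

#' ROC operating points of a scored cohort
#'
#' One operating point (1 - specificity, sensitivity) per distinct observed
#' score value used as a `>=` cut-point, plus the (0, 0) and (1, 1) anchors.
#' Points are sorted non-decreasing in both coordinates; the trapezoidal
#' area under this polyline equals the Mann-Whitney AUC.
#'
#' @param data Tibble with `total` and `died`; both classes present.
#' @return A tibble of class `roc_curve`: `cutpoint` (NA for the (0,0)
#'   anchor, which corresponds to a threshold above the maximum score),
#'   `fpr`, `tpr`.
#' @export
roc_points <- function(data) {
  n_pos <- sum(data$died); n_neg <- sum(!data$died)
  if (n_pos < 1 || n_neg < 1) {
    abort("Both outcome classes must be present to build a ROC curve.")
  }
  cuts <- sort(unique(data$total), decreasing = TRUE)
  tpr <- vapply(cuts, function(k) sum(data$died & data$total >= k) / n_pos,
                numeric(1))
  fpr <- vapply(cuts, function(k) sum(!data$died & data$total >= k) / n_neg,
                numeric(1))
  out <- tibble::tibble(
    cutpoint = c(NA_real_, as.numeric(cuts)),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- dplyr::bind_rows(out, tibble::tibble(cutpoint = NA_real_, fpr = 1, tpr = 1))
  }
  class(out) <- c("roc_curve", class(out))
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  out
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under the ROC curve
#'
#' The AUC is computed as the Mann-Whitney concordance probability — the
#' probability that a randomly chosen death outscores a randomly chosen
#' survivor, ties counted one half — via the rank-sum formula, and verified
#' internally against the trapezoidal area under [roc_points()] (the two are
#' mathematically identical). The confidence interval uses DeLong's method
#' by default (via pROC), or a seeded stratified bootstrap.
#'
#' @param data Tibble with `total` and `died`; both classes present.
#' @param level Confidence level.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap resamples (stratified by outcome), default 2000.
#' @param boot_seed Seed for the bootstrap; `NULL` uses the current RNG state.
#' @return A one-row tibble of class `auc_estimate`: `auc`, `ci_low`,
#'   `ci_high`, `level`, `method`, `n_pos`, `n_neg`.
#' @examples
#' d <- tibble::tibble(total = c(3, 4, 1, 2, 3),
#'                     died = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' auc(d)$auc  # 11/12
#' @export
auc <- function(data, level = 0.95, ci_method = c("delong", "bootstrap"),
                boot_reps = 2000, boot_seed = NULL) {
  ci_method <- match.arg(ci_method)
  n_pos <- sum(data$died); n_neg <- sum(!data$died)
  if (n_pos < 1 || n_neg < 1) {
    abort("Both outcome classes must be present to estimate an AUC.")
  }
  est <- auc_rank(data$total, data$died)
  roc <- roc_points(data)
  stopifnot(abs(est - trapezoid_area(roc$fpr, roc$tpr)) < 1e-9)

  if (ci_method == "delong") {
    # pROC advises that a degenerate AUC of 1 has interval 1-1; that is the
    # intended behaviour here, so the advisory is muffled
    ci <- withCallingHandlers(
      suppressMessages(pROC::ci.auc(
        response = data$died, predictor = data$total,
        levels = c(FALSE, TRUE), direction = "<",
        conf.level = level, method = "delong", quiet = TRUE
      )),
      warning = function(w) {
        if (grepl("AUC == 1", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    lo <- as.numeric(ci[1]); hi <- as.numeric(ci[3])
  } else {
    draw <- function() {
      pos <- sample(data$total[data$died], n_pos, replace = TRUE)
      neg <- sample(data$total[!data$died], n_neg, replace = TRUE)
      auc_rank(c(pos, neg), c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    }
    sims <- if (is.null(boot_seed)) {
      replicate(boot_reps, draw())
    } else {
      withr::with_seed(boot_seed, replicate(boot_reps, draw()))
    }
    qs <- quantile(sims, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  out <- tibble::tibble(
    auc = est, ci_low = min(lo, est), ci_high = max(hi, est), level = level,
    method = ci_method, n_pos = n_pos, n_neg = n_neg
  )
  class(out) <- c("auc_estimate", class(out))
  out
}

# Mann-Whitney AUC via midranks; ties contribute one half.
auc_rank <- function(score, died) {
  r <- rank(score)
  n_pos <- sum(died); n_neg <- sum(!died)
  (sum(r[died]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Qualitative discrimination band of an AUC
#'
#' Maps an AUC to the conventional adjective scale: excellent for AUC at or
#' above 0.90, good for 0.80-0.89, fair for 0.70-0.79, poor below 0.70. The
#' value is first rounded to two decimals (half away from zero) so a
#' computed 0.699 is labeled by its displayed value 0.70.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return Factor with levels `poor`, `fair`, `good`, `excellent`.
#' @examples
#' discrimination_label(c(0.66, 0.75, 0.91))
#' @export
discrimination_label <- function(auc) {
  if (any(is.na(auc)) || any(auc < 0 | auc > 1)) {
    abort("`auc` must lie in [0, 1].")
  }
  a <- round_half_away(auc, 2)
  out <- ifelse(a >= 0.90, "excellent",
         ifelse(a >= 0.80, "good",
         ifelse(a >= 0.70, "fair", "poor")))
  factor(out, levels = c("poor", "fair", "good", "excellent"))
}

#' Risk predictiveness curve
#'
#' Assigns every child the empirical mortality risk of their exact score
#' level (deaths at that score over children at that score), sorts children
#' by that predicted risk, and plots predicted risk against the cumulative
#' population fraction. The curve is non-decreasing by construction and its
#' population-weighted mean equals the overall cohort CFR exactly. An
#' optional pool-adjacent-violators step monotonizes risk in the score
#' itself (by default risks are the raw per-score CFRs, which need not be
#' monotone in the score).
#'
#' @param data Tibble with `total` and `died` (non-empty). A single outcome
#'   class is allowed (the curve is then flat).
#' @param monotone_in_score Apply isotonic (pool-adjacent-violators)
#'   smoothing of risk as a function of score before building the curve.
#' @return A tibble of class `predictiveness_curve`: `score_level`, `n`,
#'   `predicted_risk`, `cum_fraction`; the overall cohort CFR is attached as
#'   attribute `"overall_risk"`.
#' @export
predictiveness_curve <- function(data, monotone_in_score = FALSE) {
  if (nrow(data) == 0L) abort("Cannot build a predictiveness curve on an empty cohort.")
  by_score <- data |>
    dplyr::count(.data$total, wt = NULL, name = "n") |>
    dplyr::arrange(.data$total)
  deaths <- vapply(by_score$total,
                   function(s) sum(data$died[data$total == s]), numeric(1))
  risk <- deaths / by_score$n
  if (monotone_in_score) {
    risk <- pava_weighted(risk, by_score$n)
  }
  ord <- order(risk, by_score$total)
  out <- tibble::tibble(
    score_level = by_score$total[ord],
    n = by_score$n[ord],
    predicted_risk = risk[ord]
  )
  out$cum_fraction <- cumsum(out$n) / sum(out$n)
  class(out) <- c("predictiveness_curve", class(out))
  attr(out, "overall_risk") <- mean(data$died)
  out
}

# Pool-adjacent-violators for a weighted non-decreasing fit.
pava_weighted <- function(y, w) {
  n <- length(y)
  vals <- as.numeric(y); wts <- as.numeric(w); idx <- rep(1L, n)
  blocks <- list()
  for (i in seq_len(n)) {
    blocks[[length(blocks) + 1L]] <- list(v = vals[i], w = wts[i], size = 1L)
    while (length(blocks) > 1L) {
      k <- length(blocks)
      if (blocks[[k - 1L]]$v <= blocks[[k]]$v) break
      merged <- list(
        v = (blocks[[k - 1L]]$v * blocks[[k - 1L]]$w + blocks[[k]]$v * blocks[[k]]$w) /
          (blocks[[k - 1L]]$w + blocks[[k]]$w),
        w = blocks[[k - 1L]]$w + blocks[[k]]$w,
        size = blocks[[k - 1L]]$size + blocks[[k]]$size
      )
      blocks <- c(blocks[seq_len(k - 2L)], list(merged))
    }
  }
  unlist(lapply(blocks, function(b) rep(b$v, b$size)))
}
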