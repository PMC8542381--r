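# End-to-end external validation: filter -> score -> parameter table ->
# cut-point sweep -> AUC/ROC -> predictiveness, per score, plus a report
# bundle writer.

#' Run the full external-validation pipeline
#'
#' For each requested score: applies the complete-case age-window filter,
#' scores the eligible children, builds the per-parameter summary table, the
#' full cut-point table with recommended cut-points, the ROC curve and AUC
#' with discrimination label, and the risk predictiveness curve. A score
#' whose eligible cohort contains a single outcome class yields a partial
#' result (eligibility and parameter table only, AUC and sweep `NULL`)
#' rather than an error.
#'
#' @param x A cohort tibble (non-empty).
#' @param scores Character vector of score names (default: all three).
#' @param level Confidence level for all intervals.
#' @param perch_unresponsive_weight Passed to [score_spec()].
#' @param risc_age_window Passed to [score_spec()].
#' @param sens_range,min_spec Passed to [recommend_cutpoints()].
#' @return An object of class `pneumo_validation`: a list with one element
#'   per score (each containing `spec`, `eligibility`, `scored`,
#'   `parameter_table`, `cutpoints`, `recommended_cutpoints`, `auc`, `label`,
#'   `roc`, `predictiveness`) plus a `meta` element.
#' @examples
#' co <- simulate_cohort(default_cohort_params("perch_adapted", n = 400, seed = 3))
#' v <- run_validation(co, scores = "perch_adapted")
#' tidy(v)
#' @export
run_validation <- function(x, scores = SCORE_NAMES, level = 0.95,
                           perch_unresponsive_weight = 0,
                           risc_age_window = c(0, 25),
                           sens_range = c(0.60, 0.80), min_spec = 0.40) {
  validate_cohort(x)
  if (nrow(x) == 0L) abort("Cannot validate an empty cohort.")
  scores <- vapply(scores, match_score_name, character(1))

  per_score <- lapply(scores, function(nm) {
    spec <- score_spec(nm, risc_age_window = risc_age_window,
                       perch_unresponsive_weight = perch_unresponsive_weight)
    elig <- filter_eligible(x, spec)
    res <- list(spec = spec, eligibility = elig$report,
                exclusion_reasons = elig$reasons)
    if (nrow(elig$eligible) == 0L) {
      res$note <- "no eligible records"
      return(res)
    }
    scored <- score_cohort(elig$eligible, spec)
    res$scored <- scored
    res$parameter_table <- build_parameter_table(elig$eligible, spec, level = level)
    if (sum(scored$died) < 1 || sum(!scored$died) < 1) {
      res$note <- "single outcome class; discrimination unavailable"
      return(res)
    }
    res$cutpoints <- cutpoint_sweep(scored, spec, level = level)
    res$recommended_cutpoints <-
      recommend_cutpoints(res$cutpoints, sens_range = sens_range,
                          min_spec = min_spec)
    res$auc <- auc(scored, level = level)
    res$label <- as.character(discrimination_label(res$auc$auc))
    res$roc <- roc_points(scored)
    res$predictiveness <- predictiveness_curve(scored)
    res
  })
  names(per_score) <- scores

  structure(
    list(results = per_score,
         meta = list(n_input = nrow(x), scores = scores, level = level,
                     timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pneumo_validation"
  )
}

#' @export
print.pneumo_validation <- function(x, ...) {
  cat("<pneumo_validation> on", x$meta$n_input, "children\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat("  ", nm, ": ", r$eligibility$n_eligible, " eligible", sep = "")
    if (!is.null(r$auc)) {
      cat(sprintf(", AUC %.2f (%.2f-%.2f, %s)", r$auc$auc, r$auc$ci_low,
                  r$auc$ci_high, r$label))
    } else if (!is.null(r$note)) {
      cat(" [", r$note, "]", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Tidy a validation result
#'
#' One row per score: eligibility counts, overall CFR of the eligible
#' cohort, AUC with interval and discrimination label, and the recommended
#' cut-points collapsed to a comma-separated string.
#'
#' @param x A `pneumo_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pneumo_validation <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    cfr <- if (!is.null(r$scored)) 100 * mean(r$scored$died) else NA_real_
    tibble::tibble(
      score_name = r$spec$score_name,
      n_input = r$eligibility$n_input,
      n_eligible = r$eligibility$n_eligible,
      n_excluded_age = r$eligibility$n_excluded_age,
      n_excluded_missing = r$eligibility$n_excluded_missing,
      cfr_pct = cfr,
      auc = if (!is.null(r$auc)) r$auc$auc else NA_real_,
      auc_low = if (!is.null(r$auc)) r$auc$ci_low else NA_real_,
      auc_high = if (!is.null(r$auc)) r$auc$ci_high else NA_real_,
      label = if (!is.null(r$label)) r$label else NA_character_,
      recommended_cutpoints = if (!is.null(r$recommended_cutpoints))
        paste(r$recommended_cutpoints, collapse = ",") else NA_character_
    )
  })
}

#' Glance at a validation result
#'
#' @param x A `pneumo_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: input size, number of scores evaluated, number
#'   with discrimination available, and the confidence level used.
#' @export
glance.pneumo_validation <- function(x, ...) {
  tibble::tibble(
    n_input = x$meta$n_input,
    n_scores = length(x$results),
    n_with_auc = sum(vapply(x$results, function(r) !is.null(r$auc), logical(1))),
    level = x$meta$level
  )
}

#' Write a validation report bundle
#'
#' Writes, per score, `parameter_table.csv`, `cutpoints.csv`, `roc.csv` and
#' `predictiveness.csv` under `<out_dir>/<score_name>/`, plus a
#' machine-readable `summary.json` (eligibility, AUCs, intervals, labels,
#' recommended cut-points) and a plain-text run log at the top level.
#' Re-running on the same inputs produces byte-identical CSVs.
#'
#' @param x A `pneumo_validation` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(x, out_dir) {
  if (!inherits(x, "pneumo_validation")) abort("`x` must be a `pneumo_validation`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create output directory: ", out_dir))

  log_lines <- c(paste0("pneumoscore validation run, n_input=", x$meta$n_input))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    sub <- file.path(out_dir, nm)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(r$parameter_table)) {
      readr::write_csv(r$parameter_table, file.path(sub, "parameter_table.csv"),
                       progress = FALSE)
    }
    if (!is.null(r$cutpoints)) {
      readr::write_csv(tibble::as_tibble(r$cutpoints),
                       file.path(sub, "cutpoints.csv"), progress = FALSE)
    }
    if (!is.null(r$roc)) {
      readr::write_csv(tibble::as_tibble(r$roc), file.path(sub, "roc.csv"),
                       progress = FALSE)
    }
    if (!is.null(r$predictiveness)) {
      readr::write_csv(tibble::as_tibble(r$predictiveness),
                       file.path(sub, "predictiveness.csv"), progress = FALSE)
    }
    e <- r$eligibility
    log_lines <- c(log_lines, sprintf(
      "%s: input=%d eligible=%d excluded_age=%d excluded_missing=%d%s",
      nm, e$n_input, e$n_eligible, e$n_excluded_age, e$n_excluded_missing,
      if (!is.null(r$note)) paste0(" note=", r$note) else ""))
  }

  summary <- lapply(x$results, function(r) {
    list(
      score_name = r$spec$score_name,
      eligibility = as.list(r$eligibility),
      auc = if (!is.null(r$auc)) r$auc$auc else NULL,
      auc_ci = if (!is.null(r$auc)) c(r$auc$ci_low, r$auc$ci_high) else NULL,
      label = r$label,
      recommended_cutpoints = r$recommended_cutpoints,
      note = r$note
    )
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
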