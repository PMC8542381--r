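# The three weighted point scores and score-range enumeration.

test_that("WAZ of exactly -3 is severe under RISC but moderate under RISC-Malawi", {
  expect_equal(as.character(categorize_waz(-3, "risc")), "severe")
  expect_equal(as.character(categorize_waz(-3, "risc_malawi")), "moderate")
  expect_equal(as.character(categorize_waz(-3, "perch")), "moderate")
  expect_equal(as.character(categorize_waz(0, "risc")), "normal")
  # -2 boundary: moderate under RISC, normal under the others
  expect_equal(as.character(categorize_waz(-2, "risc")), "moderate")
  expect_equal(as.character(categorize_waz(-2, "risc_malawi")), "normal")
  expect_error(categorize_waz(NA_real_), "missing")
})

test_that("every finite WAZ maps to exactly one category", {
  waz <- c(-9.9, -3 - 1e-9, -3, -3 + 1e-9, -2 - 1e-9, -2, -2 + 1e-9, 0, 5)
  for (conv in c("risc", "risc_malawi")) {
    expect_false(anyNA(categorize_waz(waz, conv)))
  }
})

test_that("RISC worked examples reproduce the published totals", {
  r1 <- score_risc_hiv_negative(complete_record(
    "a", spo2 = 85, chest_indrawing = TRUE, wheeze = FALSE,
    refusal_to_feed = TRUE, waz = -3.5))
  expect_equal(r1$total, 6L)           # published maximum
  expect_equal(r1$pts_chest_indrawing, 0L)  # indrawing masked when SpO2 <= 90

  r2 <- score_risc_hiv_negative(complete_record(
    "b", spo2 = 95, chest_indrawing = FALSE, wheeze = TRUE,
    refusal_to_feed = FALSE, waz = 0))
  expect_equal(r2$total, -2L)          # published minimum

  r3 <- score_risc_hiv_negative(complete_record(
    "c", spo2 = 95, chest_indrawing = TRUE, wheeze = TRUE,
    refusal_to_feed = FALSE, waz = -2.5))
  expect_equal(r3$total, 1L)           # 2 - 2 + 1
})

test_that("the RISC conditional chest-indrawing rule holds for arbitrary records", {
  withr::local_seed(11)
  co <- random_complete_cohort(200)
  flipped <- co
  flipped$chest_indrawing <- !flipped$chest_indrawing
  a <- score_risc_hiv_negative(co)$total
  b <- score_risc_hiv_negative(flipped)$total
  hypox <- co$spo2 <= 90
  expect_true(all(a[hypox] == b[hypox]))
  expect_true(all(abs(a[!hypox] - b[!hypox]) == 2L))
})

test_that("RISC-Malawi worked examples reproduce the published totals", {
  expect_equal(score_risc_malawi_waz(complete_record(
    "a", spo2 = 88, waz = -3.2, sex = "female", wheeze = FALSE,
    unconscious = TRUE))$total, 17L)   # published maximum
  expect_equal(score_risc_malawi_waz(complete_record(
    "b", spo2 = 95, waz = 0, sex = "male", wheeze = FALSE,
    unconscious = FALSE))$total, 0L)
  expect_equal(score_risc_malawi_waz(complete_record(
    "c", spo2 = 91, waz = -2.5, sex = "female", wheeze = TRUE,
    unconscious = FALSE))$total, 4L)   # 1 + 3 + 1 - 1
})

test_that("SpO2 band edges are evaluated on the raw value", {
  sc <- function(s) score_risc_malawi_waz(complete_record("x", spo2 = s))$pts_spo2
  expect_equal(sc(93), 0L)
  expect_equal(sc(92.5), 1L)   # inside [90, 93)
  expect_equal(sc(90), 1L)
  expect_equal(sc(89.9), 5L)
})

test_that("adapted PERCH worked examples reproduce the published totals", {
  expect_equal(score_perch_adapted(complete_record(
    "a", age_months = 6, sex = "female", cough_history = FALSE,
    grunting = TRUE, spo2 = 90, illness_duration_days = 6, waz = -3.5,
    unconscious = FALSE))$total, 12L)  # published external maximum
  expect_equal(score_perch_adapted(complete_record(
    "b", age_months = 24, sex = "male", cough_history = TRUE,
    grunting = FALSE, spo2 = 95, illness_duration_days = 1, waz = 0,
    unconscious = FALSE))$total, -1L)  # minimum: the cough term
  r <- score_perch_adapted(complete_record(
    "c", age_months = 6, sex = "female", cough_history = TRUE,
    grunting = TRUE, spo2 = 90, illness_duration_days = 4, waz = -3.5,
    unconscious = FALSE))
  expect_equal(r$total, 11L)           # 2 + 1 - 1 + 2 + 2 + 2 + 3
  expect_equal(as.character(r$duration_band), "3-5 d")
})

test_that("the PERCH unresponsiveness weight is configurable but restricted", {
  rec <- complete_record("a", unconscious = TRUE)
  expect_equal(score_perch_adapted(rec)$pts_unconscious, 0L)
  expect_equal(score_perch_adapted(rec, unresponsive_weight = 2)$pts_unconscious, 2L)
  expect_error(score_perch_adapted(rec, unresponsive_weight = 3), "0 or 2")
})

test_that("both duration categories carry equal weight but stay distinct", {
  r35 <- score_perch_adapted(complete_record("a", illness_duration_days = 4))
  rgt5 <- score_perch_adapted(complete_record("b", illness_duration_days = 9))
  expect_equal(r35$pts_duration, rgt5$pts_duration)
  expect_false(r35$duration_band == rgt5$duration_band)
})

test_that("every total decomposes exactly into its component points", {
  withr::local_seed(21)
  co <- random_complete_cohort(150)
  for (s in c("risc_hiv_negative", "risc_malawi_waz", "perch_adapted")) {
    sc <- score_cohort(co, s)
    pts <- as.matrix(sc[grep("^pts_", names(sc))])
    expect_identical(sc$total, as.integer(rowSums(pts)))
    rng <- score_range(s)
    expect_true(all(sc$total >= rng[["min"]] & sc$total <= rng[["max"]]))
  }
})

test_that("each score ignores fields outside its required set", {
  withr::local_seed(31)
  co <- random_complete_cohort(50)
  perturb <- function(x, fields) {
    for (f in fields) {
      x[[f]] <- if (is.logical(x[[f]])) !x[[f]]
                else if (is.character(x[[f]])) ifelse(x[[f]] == "male", "female", "male")
                else x[[f]] + 1
    }
    x
  }
  for (s in c("risc_hiv_negative", "risc_malawi_waz", "perch_adapted")) {
    spec <- score_spec(s)
    all_fields <- setdiff(pneumoscore:::COHORT_COLUMNS, c("patient_id", "died"))
    irrelevant <- setdiff(all_fields, spec$required_fields)
    irrelevant <- setdiff(irrelevant, "age_months")  # age bounded; keep valid
    co2 <- perturb(co, irrelevant)
    expect_identical(score_cohort(co, s)$total, score_cohort(co2, s)$total)
  }
})

test_that("scoring an incomplete cohort names the offending field", {
  co <- complete_record("a", waz = NA_real_)
  expect_error(score_risc_malawi_waz(co), "`waz`")
  expect_error(score_perch_adapted(complete_record("b", grunting = NA)),
               "`grunting`")
})

test_that("enumerated score ranges match the published ranges", {
  expect_equal(score_range("risc_hiv_negative"), c(min = -2L, max = 6L))
  expect_equal(score_range("risc_malawi_waz"), c(min = -1L, max = 17L))
  expect_equal(score_range("perch_adapted"), c(min = -1L, max = 12L))
  # restoring the 2-point unresponsiveness weight raises the maximum to 14
  expect_equal(
    score_range(score_spec("perch_adapted", perch_unresponsive_weight = 2)),
    c(min = -1L, max = 14L))
})
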