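---
title: "Validating pediatric pneumonia mortality scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating pediatric pneumonia mortality scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumoscore)
```

# The problem

Children hospitalized with pneumonia in low-resource settings die at rates
between roughly 1% and 13% depending on presentation. Point-based risk
scores — weighted sums of bedside findings such as hypoxemia, chest
indrawing, underweight and unconsciousness — are used to concentrate
oxygen, monitoring and referral on the children most likely to die.
`pneumoscore` implements three published scores (RISC for HIV-negative
children, the weight-for-age variant of RISC-Malawi, and an adapted PERCH
score) and the statistical pipeline used to judge how well such a score
separates deaths from survivors when carried to a new population.

# The scores and their adaptations

Each scoring function reproduces its published weight table verbatim; the
achievable range is never hard-coded but recovered by `score_range()`,
which scores one synthetic child per combination of parameter categories.

Three details deserve explanation because they are easy to get wrong:

**The RISC conditional rule.** RISC gives 3 points for SpO₂ ≤ 90%. Chest
indrawing (2 points) only enters the score for children with SpO₂ > 90%;
in a hypoxemic child indrawing contributes nothing. `score_risc_hiv_negative()`
implements this as a single SpO₂-gated term, and the component columns in
its output show which branch fired. A consequence, verified by property
test: toggling indrawing never changes a hypoxemic child's total, and
changes a non-hypoxemic child's total by exactly 2.

**Two WAZ boundary conventions.** The RISC table places a weight-for-age
z-score of exactly −3 in the severe band (≤ −3), while RISC-Malawi and the
PERCH adaptation place it in the moderate band (severe is strictly < −3).
`categorize_waz()` keeps both conventions explicit; each partitions the
real line, so every finite WAZ lands in exactly one band. A WAZ of exactly
−2 is scored normal (0 points) under the RISC-Malawi/PERCH convention,
consistent with the published "≥ −2 → 0" row.

**The PERCH unresponsiveness weight.** The adaptation replaces
unresponsiveness with unconsciousness and drops "deep breathing", which the
source data cannot supply. The published external maximum is 12 — which is
only achievable if the unresponsiveness term contributes 0, since summing
all favorable weights including its 2 points gives 14. The package
therefore defaults `perch_unresponsive_weight = 0` (honouring the printed
maximum) and offers 2 as a sensitivity-analysis switch; the enumerated
maxima under the two settings are 12 and 14.

Age windows use the completed-month convention: "0–24 months" is the
half-open interval [0, 25) months, "2–59" is [2, 60), "1–59" is [1, 60). A
configuration switch widens the RISC window to [0, 60) for the
supplementary all-ages application.

# Eligibility and complete-case analysis

External validation uses a complete-case rule: a child enters a score's
validation cohort only if their age is in the score's window and every
required field is observed. `filter_eligible()` assesses age first, so a
record failing both conditions counts as an age exclusion; the counts
always satisfy n_input = n_eligible + n_excluded_age + n_excluded_missing.
The order of the two tallies is a reporting choice (the sources do not
state one); it affects only how exclusions are attributed, never who is
eligible. Missingness is always an explicit `NA`, never a sentinel value.

# Test characteristics

All proportion intervals are Clopper–Pearson exact bounds via the beta
quantile closed form: lower = qbeta(α/2; x, n−x+1), upper =
qbeta(1−α/2; x+1, n−x), with exact endpoints 0 and 1 at degenerate
numerators. The choice is deliberate: the exact interval reproduces the
published worked-example intervals (6/83 → 2.7–15.1; 508/4333 → 10.8–12.7)
at one-decimal rounding where Wilson or Wald intervals do not, and it is
conservative (coverage at least nominal, confirmed by simulation in the
test suite at p ∈ {0.02, 0.05, 0.13}, n ∈ {100, 900}).

Likelihood-ratio intervals use the standard log-variance method,
SE(ln LR⁺) = √(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)) and the symmetric
formula for LR⁻, exponentiating normal bounds. Zero cells produce flagged
`Inf`/`NaN` values rather than errors; a Haldane 0.5 continuity correction
is available but off by default, so degenerate tables are visible rather
than silently smoothed.

`cutpoint_sweep()` produces one row per integer cut-point across the
score's full enumerated range (19 rows for RISC-Malawi, −1 … 17), even
where no child attains a given total, so tables from different cohorts
align. Sensitivity is non-increasing and specificity non-decreasing in the
cut-point — an exact consequence of the ≥ classification rule that the test
suite asserts on hundreds of random cohorts. `recommend_cutpoints()`
applies the inclusive rule sensitivity ∈ [60%, 80%] with specificity ≥ 40%.

Displayed percentages round half-away-from-zero to one decimal. One known
consequence: a stratum of 917/3574 children displays as 25.7%, and exact
bounds landing precisely on a .x5 boundary (e.g. 15.651%) display one tick
above sources that truncate.

# Discrimination

The AUC is computed as the Mann–Whitney concordance probability via
midranks (ties count ½) and is asserted, inside `auc()` itself, to equal
the trapezoidal area under the empirical ROC polyline — the two are
mathematically identical, and the identity doubles as a continuous
cross-check of both code paths. The confidence interval is DeLong's by
default (via pROC, the field-standard implementation); a seeded stratified
bootstrap (default 2000 resamples) is available because the original
analyses do not name their interval method.

Qualitative bands are assigned on the value rounded to two decimals
(half-away), so a computed 0.699 is labeled by its displayed value 0.70
(fair): ≥ 0.90 excellent, 0.80–0.89 good, 0.70–0.79 fair, < 0.70 poor.

The predictiveness curve assigns each child the raw empirical CFR of their
exact score level, sorts children by that predicted risk, and plots risk
against cumulative population fraction. The population-weighted mean of
the curve equals the overall CFR exactly (it is the same sum reordered).
Raw per-score CFRs need not be monotone in the score; an optional
pool-adjacent-violators step (`monotone_in_score = TRUE`) produces the
isotonic version, which preserves the mean. The x-axis is the cumulative
fraction ordered by predicted risk (risk-percentile convention).

# The synthetic cohort generator

The patient-level data behind the published validation are not publicly
deposited, so the package ships a generator that emulates their structure:
covariates drawn independently from the published marginals of each
score's validation cohort (band probabilities for SpO₂, WAZ and illness
duration; prevalences for binary signs; cohort sizes 3574 / 17 864 / 732),
continuous values uniform within bands (SpO₂ 70–90, 90–93, 93–100; WAZ
−4.5…−3, −3…−2, and triangular with mode −0.5 on −2…1 for the normal
band), and MCAR missingness on request.

**Mortality model.** The default is an independence-calibrated
multiplicative relative-risk model: p(death) = cfr₀ · ∏ₖ rrₖ(level), where
for a binary sign with prevalence q and published stratum CFR c the
present level carries rr = c/cfr₀ and the absent level
rr = (cfr₀ − q·c)/((1−q)·cfr₀), so every factor has mean 1; multi-level
factors are renormalized likewise. With covariates independent, the
expected CFR in *every* published stratum then equals its published value
— something no single-stratum assignment scheme can achieve, because a
low-risk stratum (e.g. SpO₂ ≥ 93%, CFR 2.5%) would otherwise inherit a
mixture of the risks of whatever other strata its members occupy. The RISC
chest-indrawing factor is defined conditionally on SpO₂ > 90% (neutral,
rr = 1, in hypoxemic children) because its published stratum is the joint
one. The test suite verifies, on a seeded cohort of 20 000, that every
published RISC-Malawi prevalence and stratum CFR is recovered within three
binomial standard deviations.

A logistic alternative, P(death) = logistic(β₀ + β₁·score), drives
mortality directly through a chosen score; the suite checks that the
pipeline's empirical AUC under this model matches an exact enumeration of
the model-implied concordance to within 0.01 at n = 20 000.

**Stated simplifications.** Covariates are independent — real signs
correlate through illness severity, so joint-stratum CFRs and score
distributions in real data will differ even when every marginal matches.
Published percentages are rounded (one SpO₂ trio sums to 101%); band
weights are treated as sampling weights and normalized at draw time, while
the stored parameters keep the printed values. Quantities the sources do
not constrain are fixed once at realistic values: the SpO₂ split above 90%
in the RISC cohort (22% in 90–93), the 3–5 d / > 5 d duration split in the
PERCH cohort (50/36.5), and background prevalences of signs outside a
score's own table. Missingness is MCAR only; between-study heterogeneity
is not modeled. Passing calibration tests therefore demonstrates that the
pipeline measures what it should on data with the published margins — not
that the generator reproduces the joint behaviour of any real cohort.

# Problem sizes and determinism

Calibration and parameter-recovery checks run at n = 20 000 with fixed
seeds; distributional property tests use hundreds of small random cohorts
(n ≤ 200), sizes at which every check completes in seconds while Monte
Carlo tolerances (three binomial standard deviations; 0.01 on an AUC)
remain meaningful. All randomness flows through explicit seeds:
`simulate_cohort()` is byte-identical given its parameter seed, the
bootstrap interval takes its own seed, and `write_report()` output is
reproducible file-for-file.

# Known limitations

- The three validation cohorts cannot be reproduced numerically without
  the original pooled data; only quantities determined by printed counts
  and weights are asserted exactly.
- HIV status is not modeled: the RISC HIV-negative score is applied to all
  eligible records, as in the external application it mirrors.
- The MUAC variant of RISC-Malawi and the original (deep-breathing) PERCH
  score are out of scope; their weights are not fully published in the
  source this package follows.
- LR confidence intervals are asymptotic; with very sparse cells they are
  reported as undefined rather than approximated.
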