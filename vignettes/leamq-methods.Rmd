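---
title: "Methods: scoring, case definition and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, case definition and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind `leamq`, the choices we
made where the design was genuinely open, and what the synthetic cohort
does and does not establish about real screening data.

## The screening problem

Low energy availability (LEA) in male athletes has no practical gold
standard: direct energy-availability assessment is error-prone and
unusable at scale. The LEAM-Q screening questionnaire therefore asks about
symptoms — dizziness, gastrointestinal complaints, thermoregulation,
injury and illness, wellbeing and recovery, and (in its revised version 2)
sex drive — and is validated against a panel of clinical markers. The
package implements both halves and the statistics that connect them.

## Questionnaire scoring

Scoring is entirely key-driven. A scoring key maps each item to a section,
an allowed ordinal code range, a reverse-coding flag and a version tag
(`v1`, `v2`, `both`). The built-in default key mirrors the instrument's
section structure: 33 items on version 1, 42 on version 2 (including ten
unscored demographic items), codes 0–3 per item. The exact wording and
response options of a deployed instrument are a configuration concern:
supply your own key as YAML via `read_scoring_key()` and everything
downstream follows it.

Conventions, all chosen so that **a higher score always means a greater
likelihood of LEA**:

* positively worded wellbeing items ("I feel very energetic in general")
  are reverse-coded (`code -> max_code - code`) before summation;
* section scores are sums over *answered* items — no imputation, no
  proration; a section with no answered items is missing, never zero, and
  a completeness fraction is reported alongside;
* the total is the sum of the section scores;
* the EHMC (Exercise Hypogonadal Male Condition) composite is the sum of
  nine specific items (three sex-drive, six wellbeing) and is missing if
  any constituent is;
* low sex drive is categorical: general sex drive >= 2, or
  morning-erection frequency >= 2 together with
  erections-compared-to-normal >= 1 (version 2 only);
* weight flux is the difference of the *self-reported* highest and lowest
  body weight at current height, not measured body mass.

The "low sex drive score" is the sum of the four sex-drive items; the
listing of items 6A–6D beneath that score in the published score tables
supports this reading, but the instrument appendix was not available to
confirm it, so the key keeps it configurable.

## Clinical derivations

* **Weir energy expenditure** (abbreviated, no urinary nitrogen):
  `kcal/min = 3.941 VO2 + 1.106 VCO2`, converted with the thermochemical
  calorie, 4.184 kJ/kcal. The conversion constant affects the RMR ratio in
  the third decimal at most.
* **Cunningham (1980) predicted RMR**: `500 + 22 x FFM` kcal/day, FFM from
  DXA. The `FFM = 0` boundary returns the intercept and is documented as a
  limit, not a prediction.
* **RMR ratio**: measured RMR (kJ/day) over predicted RMR converted to
  kJ/day. Ratios outside [0.4, 1.8] trigger a unit-sanity warning.
* **Vermeulen free testosterone**: the two-binding-protein mass-action
  equilibrium with association constants `Ka = 3.6e4 L/mol` (albumin,
  43 g/L assumed when unmeasured) and `Kt = 1e9 L/mol` (SHBG) reduces to a
  quadratic in the free concentration, solved in closed form; the test
  suite checks it against an independent bisection solver to 1e-6 relative
  across TT 1–40 nmol/L and SHBG 10–100 nmol/L.

## Indicator profile and case definition

Ten clinical indicators are evaluated, four primary (low T3, low total
*or* free testosterone, BMD Z-score < -1 at either spine or femur,
BMI < 18.5) and six secondary (low RMR ratio with method-specific cutoffs
1.11 / 0.88 for first-principles / metabolic-cart, hypotension
< 90 systolic and/or < 60 diastolic, DXA body fat < 5%, low age-banded
IGF-1, LDL > 3 mmol/L, and cortisol > 550 nmol/L or
cortisol(nmol/L):insulin(pmol/L) > 26.6). The mixed cortisol:insulin units
are kept exactly as the definition prints them; no harmonisation is
applied.

Decisions worth making explicit:

* every printed cutoff is a **strict** inequality — a value exactly at the
  cutoff is never "low"/"high";
* "lowest quartile of the reference range" is operationalised as
  `low + 0.25 (high - low)` of the site's reference interval; the fixed
  printed values (3.5 pmol/L T3, 16 nmol/L total T, 333 pmol/L free T) are
  fall-backs when no site interval is configured;
* testosterone counts as **one** primary indicator whether total, free or
  both are low; the cortisol disjunction is **one** secondary indicator;
* two-branch indicators are decided leniently: one branch `TRUE` suffices
  for `met`, a known-`FALSE` branch with the other missing gives
  `not_met`, and only fully unavailable indicators are `missing`;
* IGF-1 reference intervals are age-banded (two bands, 18–34 and 35–50);
  published band edges were not available, so the bands are configuration;
* hypoglycaemia (< 4 mmol/L) and low insulin are reported descriptively
  but are *not* indicators.

Classification: athletes missing three or more indicators including at
least one primary are **excluded**; otherwise **case** when two or more
primary indicators or three or more indicators overall are met, else
**control**. The test suite proves this agrees with brute-force
enumeration of all `3^10` status assignments.

## Validation statistics

* **Reliability** is ICC(3,1): single-measure consistency from the two-way
  mixed-model ANOVA decomposition,
  `(MSR - MSE) / (MSR + (k-1) MSE)`. The instrument is fixed and the
  14-day retest may carry a constant occasion shift, which consistency
  deliberately ignores; an absolute-agreement variant is available via
  `type = "agreement"`. Confidence intervals use the Shrout–Fleiss F
  bounds. A degenerate zero between-subject variance returns 0 with a
  warning rather than NaN. Note that consistency ICC is *not* invariant
  to rescaling one administration (only to shifts); a claimed scale
  invariance fails on `retest = 2 x test`.
* **Association screen**: for every (clinical outcome, questionnaire
  variable) combination, a linear (continuous outcome) or logistic
  (low/high flag as response) model adjusted for age, BMI, elite status
  and centre — centre entering only when the complete-case rows span more
  than one centre. Complete-case per pair, per-fit `n` reported. The
  screen applies **no multiplicity correction** (unadjusted p < 0.05), so
  the report always carries the number of tests performed: with ~360
  tests, ~18 significant pairs are expected under a global null, and the
  false-positive burden must stay visible to the reader.
* **ROC / Youden**: orientation is fixed to "higher score = adverse" (the
  scoring convention guarantees it), candidate thresholds are midpoints
  between consecutive distinct observed scores, a positive call is
  `score > threshold`, and the threshold maximises
  `J = sensitivity + specificity - 1`. Ties are broken towards higher
  specificity, then the lower threshold — the selection is ranked on
  integer counts so floating-point noise cannot perturb exact ties.
  Integer scores therefore yield half-integer thresholds when adjacent
  observed scores differ by one, and gap midpoints (e.g. 2.0) otherwise.
  Binary "low"/"high" outcome states for the screen and ROC use the test
  site's lowest/highest 25% of observed results; the indicator-style
  states (low BMD, low RMR ratio) keep their fixed definitions.
* **Retention**: a questionnaire variable is retained when at least one of
  its ROC analyses reaches sensitivity >= 0.60 at the selected threshold
  (boundary inclusive).
* **Case–control comparisons** use the pooled-variance Student t-test,
  from raw values or directly from printed group summaries
  (`pooled_t_from_summary()`). Pooled, not Welch: recomputing the
  published low-sex-drive comparison from its printed summaries
  (1.96 ± 1.93, n = 77 vs 3.00 ± 2.51, n = 38) gives p ≈ 0.0156 pooled
  against the printed 0.0160, whereas Welch gives ≈ 0.028.

```{r}
library(leamq)
pooled_t_from_summary(1.96, 1.93, 77, 3.00, 2.51, 38)
```

## The synthetic cohort

No athlete-level data were deposited, so the generator *is* the study
condition for every end-to-end test. `cohort_config()` defaults encode:

* n = 310 analysed athletes across four centres; 127/310 receive
  version 2 (sex-drive items and insulin are structurally missing for
  version 1);
* a standard-normal latent severity `z` per athlete; marker `m` is
  `mean_m + sd_m (loading_m z + sqrt(1 - loading_m^2) eps)`, so marginal
  means and SDs equal the configured whole-cohort values regardless of the
  loading. Loadings are confined to the channels the validation design
  assumes severity to drive — testosterone (and derived free T), T3,
  IGF-1, insulin, cortisol, RMR ratio, BMD Z-scores, weight flux and the
  sex-drive items — with magnitudes chosen once to reproduce the published
  case/control separations (e.g. testosterone -0.55, T3 -0.60, RMR ratio
  -0.35, sex-drive item loading 0.45);
* ordinal items by thresholding a latent
  `item_loading z + section_loading f_section + eps` at the normal
  quantiles of configured marginal code frequencies, giving realistic
  within-section correlation;
* RMR-ratio marginals are method-specific (first-principles measurements
  read systematically higher: means 1.15 vs 0.95), with the method tied to
  the centre;
* missingness is missing-completely-at-random within marker blocks at the
  rates implied by the published per-variable group sizes (e.g. T3 43%,
  insulin only on version 2); albumin is missing half the time so the
  43 g/L fall-back is exercised;
* case prevalence is *emergent* from the indicator thresholds rather than
  set directly: with the default site reference ranges roughly 27%
  (seed-to-seed 23–35%) of classifiable athletes are cases and ~50 of 310
  are excluded, close to the published 32% and 45. The site reference
  intervals are themselves calibration: a universal 3.5 pmol/L T3 cutoff
  would flag ~1% of a cohort centred at 5.3 ± 0.8, irreconcilable with the
  published 17% low-T3 rate, so the per-site intervals were set once to
  reproduce the published indicator prevalences.

What the generator does **not** emulate: inter-laboratory assay bias
beyond per-centre reference intervals, DXA machine differences,
non-Gaussian marker tails, informative missingness, and item-level
response styles. Passing end-to-end tests therefore demonstrates that the
pipeline recovers structure it was designed to detect under a
linear-Gaussian severity model — not that the instrument screens well in
the field.

Test–retest pairs come from `true_i + e_ij` with
`ICC = var_true / (var_true + var_noise)`; the default targets 0.71 at
n = 42, the reliability design of the instrument's validation. Scores are
kept continuous; rounding to integer totals would bias the ICC slightly
and is not part of the model.

## Problem sizes and determinism

The simulation-based checks use 200 replicate cohorts of n = 310 for the
case–control headline, 100 null-cohort replicates through the full screen,
and 500 replicate reliability designs of n = 42 — sizes at which every
Monte-Carlo proportion asserted is stable to a few percent. All
randomness flows from explicit integer seeds; the pipeline itself draws no
random numbers, so identical inputs give byte-identical reports
(`write_report()` is deterministic in column and row order).

## Known limitations

* The default scoring key is structurally faithful (sections, subscales,
  reverse coding, version availability, EHMC membership) but its item
  wording and code ranges are package defaults, not the deployed
  instrument; real deployments must supply their key.
* The association screen inherits the design's multiplicity burden by
  construction; on a null cohort several variables are typically retained.
  Interpreting retention requires the reported test count.
* Site sample-quartile flags on small per-centre subgroups (< 4 observed
  values) are left missing rather than estimated.
* ICC confidence intervals for the agreement form reuse the consistency F
  bounds (reported as such); exact agreement intervals would require the
  occasion variance component's distribution.
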