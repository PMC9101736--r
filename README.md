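# leamq

Screening male athletes for **low energy availability (LEA)** with the
LEAM-Q questionnaire and a clinical marker panel.

Practitioners who work with endurance and weight-sensitive sport athletes
need to triage who requires clinical follow-up for LEA, but direct energy
availability assessment (intake minus exercise expenditure per kg fat-free
mass) is impractical and error-prone at scale. `leamq` implements, for
researchers and sports-medicine practitioners:

* **key-driven questionnaire scoring** — ordinal Likert-type items summed
  into section scores (dizziness, gastrointestinal, thermoregulation,
  injury/illness, wellbeing, sex drive), wellbeing subscales, a total
  score, the EHMC (Exercise Hypogonadal Male Condition) composite, a
  categorical low-sex-drive flag, and self-reported weight flux — with a
  higher score always meaning greater likelihood of LEA;
* **clinical derivations** — Weir energy expenditure
  (kcal/min = 3.941·VO₂ + 1.106·VCO₂), Cunningham predicted RMR
  (500 + 22·FFM kcal/day), the RMR ratio (measured/predicted), and
  Vermeulen calculated free testosterone (closed-form solution of the
  SHBG/albumin mass-action system, Ka = 3.6×10⁴, Kt = 10⁹ L/mol);
* **a composite case definition** — ten clinical indicators (four primary:
  low T₃, low total/free testosterone, BMD Z < −1, BMI < 18.5; six
  secondary: low RMR ratio, hypotension, low body fat, low IGF-1, high
  LDL, high cortisol or cortisol:insulin ratio), classifying each athlete
  as **case** (≥2 primary or ≥3 indicators overall), **control**, or
  **excluded** (≥3 indicators missing, ≥1 primary);
* **the validation pipeline** — test–retest reliability via ICC(3,1)
  (two-way mixed, single-measure consistency:
  (MS_R − MS_E)/(MS_R + MS_E)) with unreliable-item removal; a
  covariate-adjusted (age, BMI, elite, centre) linear/logistic association
  screen over all outcome×predictor combinations; ROC analysis with
  Youden-index threshold selection (J = sensitivity + specificity − 1) and
  a ≥60% sensitivity retention rule; pooled two-sample t case–control
  comparisons, including directly from printed group summaries;
* **a calibrated synthetic cohort generator** — a latent-severity model
  reproducing the published cohort's marginals, case/control separations,
  version split and block missingness, so every stage is testable without
  athlete data.

## Worked example

```r
library(leamq)

# a synthetic multi-centre cohort of 310 athletes (183 v1 / 127 v2 forms)
co  <- generate_cohort(cohort_config(n = 310, seed = 1))
res <- run_validation_pipeline(co$responses, co$clinical, seed = 1)
res
#> LEAM-Q validation pipeline
#>   athletes: 310 (cases 76 / controls 177 / excluded 57)
#>   association screen: 360 tests at p < 0.05, 27 significant
#>   retained variables (sensitivity >= 60%): fatigue, low_energy,
#>     low_sex_drive_score, poor_recovery, s6a, s6c
```

57 athletes are excluded for missing ≥3 clinical indicators; of the 253
classifiable, 76 (30%) meet the composite LEA case definition. The screen
reports its 360 unadjusted tests so the false-positive burden stays
visible. Among section scores, only sex drive separates cases from
controls:

```r
res$score_comparisons[c(1, 5, 6), c("variable", "mean1", "n1", "mean2", "n2", "p_value")]
#>    variable mean1  n1  mean2 n2 p_value
#> 1 dizziness  0.87 177  0.803 76 0.64082
#> 5 wellbeing 16.14 177 17.118 76 0.26766
#> 6 sex_drive  2.03  74  3.256 43 0.00429
```

(cases score ~1.2 points higher on the 0–12 sex-drive section; dizziness
and wellbeing do not differ). The same t-test works straight from printed
group summaries — here the published low-sex-drive case/control row:

```r
pooled_t_from_summary(1.96, 1.93, 77, 3.00, 2.51, 38)
#>   mean1  sd1 n1 mean2  sd2 n2     t  df p_value                test
#> 1  1.96 1.93 77     3 2.51 38 -2.45 113  0.0156 pooled two-sample t
```

Reliability of a 42-subject, 14-day test–retest design targeting
ICC 0.71:

```r
d <- generate_test_retest(test_retest_config(n = 42, icc = 0.71, seed = 1))
icc_test_retest(d$test, d$retest)
#> ICC(3,1) consistency = 0.608  (95% CI 0.376-0.768), two-way mixed,
#>   single measure, n = 42, k = 2
```

`write_report(res, "out/")` writes the association, ROC, comparison and
classification tables as CSV plus a JSON run manifest. A thin CLI wrapper
with `simulate` / `score` / `classify` / `validate` subcommands ships at
`system.file("cli", "leamq.R", package = "leamq")`.

See `vignettes/leamq-methods.Rmd` for the model, the threshold
conventions (strict inequalities, reference-range vs sample quartiles),
and what the synthetic cohort does and does not establish.

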