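#' Reference configuration for clinical indicator thresholds
#'
#' Encodes the operational definitions of the clinical indicators of low
#' energy availability: four primary indicators (low T3, low total or free
#' testosterone, low BMD, underweight) and six secondary indicators (low
#' RMR ratio, hypotension, low body fat, low IGF-1, high LDL cholesterol,
#' high cortisol or cortisol:insulin ratio).
#'
#' Blood analytes are called "low" when they fall strictly below the lowest
#' quartile of the reference range of the site where the sample was
#' analysed, operationalised as `low + 0.25 * (high - low)` of the site's
#' reference interval. When no site interval is configured the fixed
#' fall-back cutoffs apply: T3 < 3.5 pmol/L, total testosterone
#' < 16 nmol/L, free testosterone < 333 pmol/L. Fixed-threshold indicators
#' are BMD Z-score < -1 at either the AP spine or proximal femur,
#' BMI < 18.5 kg/m2, blood pressure < 90 mmHg systolic and/or < 60 mmHg
#' diastolic, DXA body fat < 5%, LDL > 3 mmol/L, and cortisol > 550 nmol/L
#' or cortisol(nmol/L):insulin(pmol/L) ratio > 26.6. The RMR-ratio cutoff
#' is measurement-method specific: < 1.11 for first-principles (Douglas
#' bag) and < 0.88 for metabolic-cart measurements, the lowest observed
#' quartile of each method. All cutoffs are strict inequalities.
#'
#' @return a list with components `fixed` (fixed thresholds),
#'   `rmr_ratio_low` (named per-method cutoffs), `default_low` (fall-back
#'   analyte cutoffs) and `centres` (per-centre reference intervals and
#'   age-banded IGF-1 intervals). The default configures the four study
#'   centres of the synthetic cohort.
#' @seealso [build_indicator_profile()], [read_reference_config()]
#' @export
default_reference_config <- function() {
  centre <- function(t3, tt = c(10, 34), ft = c(200, 732),
                     insulin = c(9, 43),
                     igf1_young = c(14, 54), igf1_old = c(10, 50)) {
    list(ranges = list(t3 = t3, total_testosterone = tt,
                       free_testosterone = ft, insulin = insulin),
         igf1_age_bands = data.frame(
           age_min = c(18, 35), age_max = c(34, 50),
           low = c(igf1_young[1], igf1_old[1]),
           high = c(igf1_young[2], igf1_old[2])))
  }
  list(
    fixed = list(bmi_underweight = 18.5, bmd_z_low = -1,
                 bp_systolic_low = 90, bp_diastolic_low = 60,
                 body_fat_low = 5, ldl_high = 3, cortisol_high = 550,
                 cortisol_insulin_ratio_high = 26.6,
                 hypoglycaemia = 4.0),
    rmr_ratio_low = c(first_principles = 1.11, metabolic_cart = 0.88),
    default_low = list(t3 = 3.5, total_testosterone = 16,
                       free_testosterone = 333),
    centres = list(
      canberra     = centre(t3 = c(3.7, 6.7)),
      oslo         = centre(t3 = c(3.9, 6.7)),
      kristiansand = centre(t3 = c(3.9, 6.7)),
      copenhagen   = centre(t3 = c(3.8, 6.6))
    )
  )
}

## lowest quartile of a reference interval
quartile_cutoff <- function(range) {
  if (is.null(range)) return(NULL)
  if (range[2] <= range[1]) stop_config("reference interval must have low < high")
  range[1] + 0.25 * (range[2] - range[1])
}

## per-athlete "low" cutoff for an analyte, honouring site ranges with the
## printed defaults as fall-back; unknown centres are a configuration error
analyte_low_cutoff <- function(analyte, centres_vec, ref) {
  vapply(centres_vec, function(cn) {
    if (is.na(cn) || !nzchar(cn)) {
      return(ref$default_low[[analyte]] %||% NA_real_)
    }
    site <- ref$centres[[cn]]
    if (is.null(site)) stop_config("centre not in reference config: ", cn)
    q <- quartile_cutoff(site$ranges[[analyte]])
    if (is.null(q)) ref$default_low[[analyte]] %||% NA_real_ else q
  }, numeric(1))
}

igf1_low_cutoff <- function(centres_vec, ages, ref) {
  mapply(function(cn, age) {
    if (is.na(cn) || !nzchar(cn) || is.na(age)) return(NA_real_)
    site <- ref$centres[[cn]]
    if (is.null(site)) stop_config("centre not in reference config: ", cn)
    bands <- site$igf1_age_bands
    hit <- which(age >= bands$age_min & age <= bands$age_max)
    if (!length(hit)) return(NA_real_)
    quartile_cutoff(c(bands$low[hit[1]], bands$high[hit[1]]))
  }, centres_vec, ages)
}

#' Build clinical indicator profiles
#'
#' Applies the indicator definitions of [default_reference_config()] to a
#' derived clinical panel and returns, per athlete, the status of each of
#' the ten indicators (`"met"`, `"not_met"` or `"missing"`) together with
#' the tallies used by [classify_lea()].
#'
#' For two-branch indicators (testosterone total/free, BMD spine/femur,
#' blood pressure systolic/diastolic, cortisol/cortisol:insulin ratio) a
#' single `TRUE` branch sets the indicator `met`; the indicator is
#' `missing` only when every branch is unavailable.
#'
#' @param panel a clinical panel passed through [derive_clinical()];
#'   columns in the units documented there. A `centre` column selects the
#'   site reference intervals.
#' @param ref a reference configuration list.
#' @return a data frame with one row per athlete: `athlete_id`, ten status
#'   columns, `n_primary_met`, `n_total_met`, `n_missing`,
#'   `n_primary_missing`, and descriptive flags (`hypoglycaemia`,
#'   `low_insulin`) that are not part of the indicator count.
#' @export
build_indicator_profile <- function(panel, ref = default_reference_config()) {
  panel <- derive_clinical(panel)
  n <- nrow(panel)
  col <- function(name) if (name %in% names(panel)) panel[[name]] else
    rep(NA_real_, n)
  centres <- if ("centre" %in% names(panel)) as.character(panel$centre) else
    rep(NA_character_, n)

  low_t3 <- lt(col("t3"), analyte_low_cutoff("t3", centres, ref))
  low_tt <- lt(col("total_testosterone"),
               analyte_low_cutoff("total_testosterone", centres, ref))
  low_ft <- lt(col("free_testosterone"),
               analyte_low_cutoff("free_testosterone", centres, ref))
  low_testosterone <- mapply(or_lenient, low_tt, low_ft)
  low_bmd <- mapply(or_lenient,
                    lt(col("spine_bmd_z"), ref$fixed$bmd_z_low),
                    lt(col("femur_bmd_z"), ref$fixed$bmd_z_low))
  underweight <- lt(col("bmi"), ref$fixed$bmi_underweight)

  method <- if ("rmr_method" %in% names(panel))
    as.character(panel$rmr_method) else rep(NA_character_, n)
  rmr_cut <- ref$rmr_ratio_low[method]
  low_rmr <- lt(col("rmr_ratio"), unname(rmr_cut))
  hypotension <- mapply(or_lenient,
                        lt(col("systolic_bp"), ref$fixed$bp_systolic_low),
                        lt(col("diastolic_bp"), ref$fixed$bp_diastolic_low))
  low_body_fat <- lt(col("body_fat_pct"), ref$fixed$body_fat_low)
  low_igf1 <- lt(col("igf1"), igf1_low_cutoff(centres, col("age"), ref))
  high_ldl <- gt(col("ldl"), ref$fixed$ldl_high)
  high_cortisol <- mapply(or_lenient,
                          gt(col("cortisol"), ref$fixed$cortisol_high),
                          gt(col("cortisol_insulin_ratio"),
                             ref$fixed$cortisol_insulin_ratio_high))

  status <- function(x) ifelse(is.na(x), "missing",
                               ifelse(x, "met", "not_met"))
  out <- data.frame(
    athlete_id = if ("athlete_id" %in% names(panel)) panel$athlete_id else
      as.character(seq_len(n)),
    low_t3 = status(low_t3),
    low_testosterone = status(low_testosterone),
    low_bmd = status(low_bmd),
    underweight = status(underweight),
    low_rmr_ratio = status(low_rmr),
    hypotension = status(hypotension),
    low_body_fat = status(low_body_fat),
    low_igf1 = status(low_igf1),
    high_ldl = status(high_ldl),
    high_cortisol_or_ratio = status(high_cortisol),
    stringsAsFactors = FALSE)
  out <- add_indicator_counts(out)
  ## descriptive flags, not indicators
  out$hypoglycaemia <- lt(col("glucose"), ref$fixed$hypoglycaemia)
  out$low_insulin <- lt(col("insulin"),
                        analyte_low_cutoff("insulin", centres, ref))
  out
}

primary_indicators <- function() {
  c("low_t3", "low_testosterone", "low_bmd", "underweight")
}

secondary_indicators <- function() {
  c("low_rmr_ratio", "hypotension", "low_body_fat", "low_igf1", "high_ldl",
    "high_cortisol_or_ratio")
}

add_indicator_counts <- function(profile) {
  prim <- as.matrix(profile[, primary_indicators(), drop = FALSE])
  all10 <- as.matrix(profile[, c(primary_indicators(),
                                 secondary_indicators()), drop = FALSE])
  profile$n_primary_met <- rowSums(prim == "met")
  profile$n_total_met <- rowSums(all10 == "met")
  profile$n_missing <- rowSums(all10 == "missing")
  profile$n_primary_missing <- rowSums(prim == "missing")
  profile
}

#' Classify athletes as LEA case, control or excluded
#'
#' Applies the composite case definition to an indicator profile: an
#' athlete missing at least three of the ten clinical indicators, at least
#' one of them primary, is excluded from classification; otherwise they are
#' a case when two or more primary indicators or three or more indicators
#' overall are met, and a control when neither condition holds.
#'
#' @param profile a data frame from [build_indicator_profile()] (the count
#'   columns are recomputed from the statuses if absent).
#' @return a data frame with `athlete_id`, `verdict`
#'   (`"case"`/`"control"`/`"excluded"`) and a human-readable `reason`.
#' @examples
#' prof <- data.frame(low_t3 = "met", low_testosterone = "met",
#'                    low_bmd = "not_met", underweight = "not_met",
#'                    low_rmr_ratio = "not_met", hypotension = "not_met",
#'                    low_body_fat = "not_met", low_igf1 = "not_met",
#'                    high_ldl = "not_met", high_cortisol_or_ratio = "not_met")
#' classify_lea(prof)$verdict   # "case": two primary indicators met
#' @export
classify_lea <- function(profile) {
  if (!all(c("n_primary_met", "n_total_met", "n_missing",
             "n_primary_missing") %in% names(profile))) {
    profile <- add_indicator_counts(profile)
  }
  excluded <- profile$n_missing >= 3 & profile$n_primary_missing >= 1
  case <- profile$n_primary_met >= 2 | profile$n_total_met >= 3
  verdict <- ifelse(excluded, "excluded", ifelse(case, "case", "control"))
  reason <- ifelse(excluded,
                   sprintf("%d indicators missing (%d primary)",
                           profile$n_missing, profile$n_primary_missing),
                   ifelse(case,
                          sprintf("%d primary / %d total indicators met",
                                  profile$n_primary_met, profile$n_total_met),
                          sprintf("below case thresholds (%d primary / %d total met)",
                                  profile$n_primary_met, profile$n_total_met)))
  data.frame(
    athlete_id = if ("athlete_id" %in% names(profile)) profile$athlete_id else
      as.character(seq_len(nrow(profile))),
    verdict = verdict, reason = reason, stringsAsFactors = FALSE)
}
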