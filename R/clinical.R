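#' Weir energy expenditure from respiratory gas exchange
#'
#' Abbreviated Weir equation (no urinary nitrogen):
#' `kcal/min = 3.941 * VO2 + 1.106 * VCO2`, converted to kJ/min with the
#' thermochemical calorie (4.184 kJ/kcal).
#'
#' @param vo2,vco2 oxygen consumption and carbon dioxide production, L/min.
#' @return energy expenditure in kJ/min.
#' @examples
#' weir_energy_expenditure(0.25, 0.20)   # ~5.05 kJ/min
#' @export
weir_energy_expenditure <- function(vo2, vco2) {
  stopifnot(all(vo2 >= 0, na.rm = TRUE), all(vco2 >= 0, na.rm = TRUE))
  rq <- vco2 / vo2
  if (any(!is.na(rq) & is.finite(rq) & (rq < 0.6 | rq > 1.3))) {
    warning("respiratory quotient outside [0.6, 1.3]: check gas data",
            call. = FALSE)
  }
  (3.941 * vo2 + 1.106 * vco2) * 4.184
}

#' Cunningham (1980) predicted resting metabolic rate
#'
#' `RMR_pred [kcal/day] = 500 + 22 * FFM [kg]`, with fat-free (lean body)
#' mass from DXA.
#'
#' @param ffm fat-free mass in kg (non-negative; the value at the `ffm = 0`
#'   boundary is the intercept 500 kcal/day, a documented limit rather than
#'   a physiological prediction).
#' @return predicted RMR in kcal/day.
#' @export
cunningham_predicted_rmr <- function(ffm) {
  stopifnot(all(ffm >= 0, na.rm = TRUE))
  500 + 22 * ffm
}

#' RMR ratio: measured over Cunningham-predicted resting metabolic rate
#'
#' The predicted value (kcal/day) is converted to kJ/day with 4.184 so both
#' sides share units. A suppressed ratio suggests energy deficiency.
#'
#' @param measured measured RMR in kJ/day.
#' @param predicted Cunningham-predicted RMR in kcal/day.
#' @return dimensionless ratio.
#' @export
rmr_ratio <- function(measured, predicted) {
  stopifnot(all(measured > 0, na.rm = TRUE), all(predicted > 0, na.rm = TRUE))
  ratio <- measured / (predicted * 4.184)
  if (any(!is.na(ratio) & (ratio < 0.4 | ratio > 1.8))) {
    warning("RMR ratio outside [0.4, 1.8]: check input units", call. = FALSE)
  }
  ratio
}

#' Vermeulen calculated free testosterone
#'
#' Solves the two-binding-protein mass-action equilibrium for free
#' testosterone given total testosterone, SHBG and albumin, with
#' association constants `Ka = 3.6e4 L/mol` for albumin and
#' `Kt = 1e9 L/mol` for SHBG. Where albumin is unmeasured the conventional
#' 43 g/L is assumed. The equilibrium reduces to a quadratic in the free
#' concentration, solved in closed form:
#' \deqn{N K_t \cdot FT^2 + (N + K_t(SHBG - TT)) \cdot FT - TT = 0,}
#' with `N = 1 + Ka * [albumin]`.
#'
#' @param tt total testosterone, nmol/L.
#' @param shbg sex hormone binding globulin, nmol/L.
#' @param albumin albumin, g/L (default 43).
#' @return free testosterone in pmol/L. Vectorised over inputs.
#' @examples
#' vermeulen_free_testosterone(20, 40)        # ~382 pmol/L, ~1.9% free
#' @export
vermeulen_free_testosterone <- function(tt, shbg, albumin = 43) {
  stopifnot(all(tt >= 0, na.rm = TRUE), all(shbg >= 0, na.rm = TRUE),
            all(albumin > 0, na.rm = TRUE))
  Ka <- 3.6e4; Kt <- 1e9
  TT <- tt * 1e-9; SHBG <- shbg * 1e-9
  N <- 1 + Ka * albumin / 69000          # albumin MW 69 kDa
  a <- N * Kt
  b <- N + Kt * (SHBG - TT)
  disc <- b^2 + 4 * a * TT
  if (any(!is.na(disc) & disc < 0)) {
    stop("free-testosterone solve failed (negative discriminant) for tt=",
         tt, " shbg=", shbg, " albumin=", albumin)
  }
  ft <- (-b + sqrt(disc)) / (2 * a)      # positive root
  ft * 1e12                              # mol/L -> pmol/L
}

#' Derive clinical quantities for a cohort panel
#'
#' Fills in derived columns used by the indicator rules and the validation
#' pipeline: BMI (from mass and height when absent), calculated free
#' testosterone (Vermeulen, when total testosterone and SHBG are present),
#' Cunningham-predicted RMR, the RMR ratio, RMR per kg fat-free mass, and
#' the hormone ratios (cortisol:insulin, free testosterone:cortisol, total
#' testosterone:cortisol). Ratio units follow the reporting convention of
#' the clinical panel: cortisol in nmol/L, insulin in pmol/L, free
#' testosterone in pmol/L; no unit harmonisation is applied.
#'
#' @param panel a clinical panel data frame (see [read_clinical_panel()]
#'   for the column schema).
#' @return the panel with derived columns added (existing measured values
#'   are never overwritten).
#' @export
derive_clinical <- function(panel) {
  n <- nrow(panel)
  col <- function(name) if (name %in% names(panel)) panel[[name]] else
    rep(NA_real_, n)

  bmi <- col("bmi")
  h_m <- col("height") / 100
  bmi_calc <- col("body_mass") / h_m^2
  panel$bmi <- ifelse(is.na(bmi), bmi_calc, bmi)

  ft <- col("free_testosterone")
  can_calc <- is.na(ft) & !is.na(col("total_testosterone")) &
    !is.na(col("shbg"))
  if (any(can_calc)) {
    alb <- ifelse(is.na(col("albumin")), 43, col("albumin"))
    ft[can_calc] <- vermeulen_free_testosterone(
      col("total_testosterone")[can_calc], col("shbg")[can_calc],
      alb[can_calc])
  }
  panel$free_testosterone <- ft

  ffm <- col("ffm")
  pred <- ifelse(is.na(ffm) | ffm <= 0, NA_real_,
                 500 + 22 * ffm)                     # kcal/day
  panel$rmr_predicted_kcal <- pred
  meas <- col("rmr_measured")
  panel$rmr_ratio <- ifelse(is.na(meas) | is.na(pred), NA_real_,
                            meas / (pred * 4.184))
  panel$rmr_kj_per_kg_ffm <- ifelse(is.na(meas) | is.na(ffm), NA_real_,
                                    meas / ffm)

  panel$cortisol_insulin_ratio <- col("cortisol") / col("insulin")
  panel$free_t_cortisol_ratio <- panel$free_testosterone / col("cortisol")
  panel$tt_cortisol_ratio <- col("total_testosterone") / col("cortisol")
  panel
}
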