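#' Options for the validation pipeline
#'
#' @param p_threshold unadjusted significance threshold of the association
#'   screen (default 0.05).
#' @param min_sensitivity minimum ROC sensitivity for a questionnaire
#'   variable to be retained (default 0.60, boundary inclusive).
#' @param icc_cutoff test-retest ICC below which an item is removed.
#' @param covariates adjustment set for the association screen.
#' @param outcomes,predictors optional explicit column sets for the
#'   screen; the defaults cover the full clinical panel (continuous
#'   markers plus their low/high flags) against every questionnaire
#'   section score, wellbeing subscale, sex-drive item and composite.
#' @return list of class `leamq_pipeline_config`.
#' @export
pipeline_config <- function(p_threshold = 0.05, min_sensitivity = 0.60,
                            icc_cutoff = 0.5,
                            covariates = c("age", "bmi", "elite", "centre"),
                            outcomes = NULL, predictors = NULL) {
  structure(list(p_threshold = p_threshold,
                 min_sensitivity = min_sensitivity,
                 icc_cutoff = icc_cutoff, covariates = covariates,
                 outcomes = outcomes, predictors = predictors),
            class = "leamq_pipeline_config")
}

## adverse direction of each continuous clinical outcome ("low" = values
## fall with worsening energy status) and the flag column used for its ROC
continuous_outcomes <- function() {
  c(glucose = "low", insulin = "low", cortisol = "high",
    total_testosterone = "low", free_testosterone = "low", t3 = "low",
    igf1 = "low", total_chol = "high", ldl = "high", hdl = "high",
    triglycerides = "high", spine_bmd_z = "low", femur_bmd_z = "low",
    rmr_ratio = "low", cortisol_insulin_ratio = "high",
    free_t_cortisol_ratio = "low", tt_cortisol_ratio = "low")
}

default_predictors <- function() {
  c("dizziness", "gastrointestinal", "thermoregulation", "injury_illness",
    "wellbeing", "fatigue", "poor_recovery", "low_energy",
    "s6a", "s6b", "s6c", "s6d", "low_sex_drive_score", "ehmc_score",
    "weight_flux_kg")
}

section_scores <- function() {
  c("dizziness", "gastrointestinal", "thermoregulation", "injury_illness",
    "wellbeing", "sex_drive")
}

## strict site-sample quartile flag: the centre's lowest (or highest) 25%
## of observed values
site_quartile_flag <- function(values, centres, direction = c("low", "high")) {
  direction <- match.arg(direction)
  centres <- as.character(centres)
  centres[is.na(centres)] <- "(none)"
  out <- rep(NA, length(values))
  for (cn in unique(centres)) {
    i <- centres == cn
    v <- values[i]
    if (sum(!is.na(v)) < 4) next
    if (direction == "low") {
      out[i] <- v < stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE)
    } else {
      out[i] <- v > stats::quantile(v, 0.75, na.rm = TRUE, names = FALSE)
    }
  }
  out
}

#' Assemble the per-athlete analysis table
#'
#' Joins scored questionnaire responses with the derived clinical panel
#' and adds the binary low/high outcome flags used by the association
#' screen and the ROC analyses: indicator-style flags for low BMD and low
#' RMR ratio, and strict site-sample quartile flags for the blood
#' variables (the site's lowest or highest 25% of observed results).
#'
#' @param scores output of [score_responses()].
#' @param clinical a clinical panel (passed through [derive_clinical()]).
#' @param ref reference configuration.
#' @return merged data frame, one row per athlete.
#' @export
build_analysis_table <- function(scores, clinical,
                                 ref = default_reference_config()) {
  clin <- derive_clinical(clinical)
  d <- merge(scores, clin, by = "athlete_id", all = TRUE, sort = TRUE)
  ctr <- if ("centre" %in% names(d)) d$centre else rep(NA_character_, nrow(d))
  d$flag_low_t3 <- site_quartile_flag(d$t3, ctr, "low")
  d$flag_low_insulin <- site_quartile_flag(d$insulin, ctr, "low")
  d$flag_high_cortisol <- site_quartile_flag(d$cortisol, ctr, "high")
  d$flag_high_cortisol_insulin_ratio <-
    site_quartile_flag(d$cortisol_insulin_ratio, ctr, "high")
  d$flag_low_free_t_cortisol_ratio <-
    site_quartile_flag(d$free_t_cortisol_ratio, ctr, "low")
  d$flag_low_rmr_ratio <- {
    cut <- ref$rmr_ratio_low[as.character(d$rmr_method)]
    ifelse(is.na(d$rmr_ratio) | is.na(cut), NA, d$rmr_ratio < cut)
  }
  d$flag_low_bmd <- mapply(or_lenient,
                           lt(d$spine_bmd_z, ref$fixed$bmd_z_low),
                           lt(d$femur_bmd_z, ref$fixed$bmd_z_low))
  d
}

#' Run the full questionnaire-validation pipeline
#'
#' Orchestrates the analysis end-to-end: questionnaire scoring, clinical
#' derivation, indicator profiling and LEA case/control/excluded
#' classification, the covariate-adjusted association screen over all
#' outcome-predictor combinations, ROC/Youden threshold selection for the
#' significantly associated questionnaire variables, the
#' minimum-sensitivity retention rule, and case-control comparisons of
#' questionnaire variables and subject characteristics. Deterministic
#' given its inputs.
#'
#' @param responses questionnaire response table (see [read_responses()]).
#' @param clinical clinical panel table.
#' @param key scoring key.
#' @param ref reference configuration.
#' @param config a [pipeline_config()].
#' @param seed integer recorded in the manifest (the pipeline itself draws
#'   no random numbers).
#' @return object of class `leamq_validation`: list with `scores`,
#'   `classification`, `exclusions`, `profile`, `associations` (with
#'   attribute `n_tests`), `roc`, `retained`, `score_comparisons`,
#'   `characteristics` and `manifest`.
#' @export
run_validation_pipeline <- function(responses, clinical,
                                    key = default_scoring_key(),
                                    ref = default_reference_config(),
                                    config = pipeline_config(),
                                    seed = NA_integer_) {
  key <- as_scoring_key(key)
  scores <- score_responses(responses, key)
  profile <- if (nrow(clinical)) build_indicator_profile(clinical, ref) else
    NULL
  classification <- if (!is.null(profile)) classify_lea(profile) else
    data.frame(athlete_id = character(0), verdict = character(0),
               reason = character(0))
  exclusions <- classification[classification$verdict == "excluded", ,
                               drop = FALSE]
  item_cols <- intersect(c("s6a", "s6b", "s6c", "s6d"), names(responses))
  if (length(item_cols)) {
    scores <- merge(scores,
                    responses[, c("athlete_id", item_cols), drop = FALSE],
                    by = "athlete_id", sort = TRUE)
  }
  d <- build_analysis_table(scores, clinical, ref)
  d <- merge(d, classification[, c("athlete_id", "verdict")],
             by = "athlete_id", all.x = TRUE, sort = TRUE)

  outcomes <- config$outcomes %||% {
    cont <- intersect(names(continuous_outcomes()), names(d))
    flags <- intersect(c("flag_low_t3", "flag_low_insulin",
                         "flag_high_cortisol",
                         "flag_high_cortisol_insulin_ratio",
                         "flag_low_free_t_cortisol_ratio",
                         "flag_low_rmr_ratio", "flag_low_bmd"), names(d))
    c(cont, flags)
  }
  predictors <- config$predictors %||%
    intersect(default_predictors(), names(d))

  associations <- if (nrow(d) && length(outcomes) && length(predictors)) {
    association_screen(d, outcomes, predictors, config$covariates)
  } else {
    structure(data.frame(outcome = character(0), predictor = character(0),
                         model = character(0), slope = numeric(0),
                         se = numeric(0), p_value = numeric(0),
                         n = integer(0), covariates = character(0),
                         note = character(0)), n_tests = 0L)
  }
  n_tests <- attr(associations, "n_tests")

  sig <- associations[!is.na(associations$p_value) &
                        associations$p_value < config$p_threshold, ,
                      drop = FALSE]
  roc_tab <- roc_for_significant(d, sig, config$min_sensitivity)
  retained <- retain_variables(roc_tab, config$min_sensitivity)

  grp <- d$verdict
  cc <- function(var) {
    r <- compare_groups(d[[var]][grp %in% c("control", "case")],
                        factor(grp[grp %in% c("control", "case")],
                               levels = c("control", "case")),
                        variable = var)
    r
  }
  score_vars <- unique(c(section_scores()[section_scores() %in% names(d)],
                         predictors))
  empty_cmp <- pooled_t_from_summary(0, 1, 2, 0, 1, 2)[0, , drop = FALSE]
  score_comparisons <- if (any(grp %in% "case") && any(grp %in% "control")) {
    out <- do.call(rbind, lapply(score_vars, cc))
    out$retained <- out$variable %in% retained
    out
  } else {
    cbind(empty_cmp, retained = logical(0))
  }
  char_vars <- intersect(c("age", "height", "body_mass", "bmi",
                           "weight_flux_kg", "body_fat_pct", "ffm",
                           "spine_bmd_z", "femur_bmd_z", "systolic_bp",
                           "diastolic_bp", "rmr_kj_per_kg_ffm", "rmr_ratio",
                           "total_testosterone", "free_testosterone",
                           "free_t_cortisol_ratio", "tt_cortisol_ratio",
                           "igf1", "t3", "cortisol", "insulin", "glucose",
                           "total_chol", "ldl", "hdl", "triglycerides"),
                         names(d))
  characteristics <- if (nrow(score_comparisons)) {
    do.call(rbind, lapply(char_vars, cc))
  } else {
    empty_cmp
  }

  manifest <- list(
    seed = seed,
    n_input = nrow(responses),
    n_classified = sum(classification$verdict != "excluded"),
    n_cases = sum(classification$verdict == "case"),
    n_controls = sum(classification$verdict == "control"),
    n_excluded = nrow(exclusions),
    n_association_tests = n_tests,
    p_threshold = config$p_threshold,
    min_sensitivity = config$min_sensitivity,
    config_hash = object_hash(unclass(config)),
    package_version = as.character(utils::packageVersion("leamq")))

  structure(list(scores = scores, profile = profile,
                 classification = classification, exclusions = exclusions,
                 data = d, associations = associations, roc = roc_tab,
                 retained = retained,
                 score_comparisons = score_comparisons,
                 characteristics = characteristics, manifest = manifest),
            class = "leamq_validation")
}

## ROC per significant (outcome, predictor) pair, against the binary flag
## version of the outcome
roc_for_significant <- function(d, sig, min_sensitivity) {
  empty <- data.frame(predictor = character(0), outcome = character(0),
                      flag = character(0), threshold = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      youden_j = numeric(0), retained = logical(0),
                      n_pos = integer(0), n_neg = integer(0))
  if (!nrow(sig)) return(empty)
  dirs <- continuous_outcomes()
  flag_of <- function(outcome) {
    if (startsWith(outcome, "flag_")) return(outcome)
    if (outcome %in% c("spine_bmd_z", "femur_bmd_z")) return("flag_low_bmd")
    if (outcome == "rmr_ratio") return("flag_low_rmr_ratio")
    candidate <- paste0("flag_", dirs[outcome], "_", outcome)
    if (candidate %in% names(d)) candidate else NA_character_
  }
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    fl <- flag_of(sig$outcome[i])
    flag_vals <- if (!is.na(fl) && fl %in% names(d)) d[[fl]] else {
      v <- d[[sig$outcome[i]]]
      dir <- dirs[sig$outcome[i]]
      site_quartile_flag(v, d$centre %||% rep(NA, nrow(d)),
                         if (is.na(dir)) "high" else dir)
    }
    keep <- !is.na(d[[sig$predictor[i]]]) & !is.na(flag_vals)
    if (sum(flag_vals[keep]) == 0 || sum(!flag_vals[keep]) == 0) return(NULL)
    r <- suppressWarnings(roc_youden(d[[sig$predictor[i]]][keep],
                                     flag_vals[keep], min_sensitivity))
    data.frame(predictor = sig$predictor[i], outcome = sig$outcome[i],
               flag = fl %||% NA_character_, threshold = r$threshold,
               sensitivity = r$sensitivity, specificity = r$specificity,
               youden_j = r$youden_j, retained = r$retained,
               n_pos = r$n_pos, n_neg = r$n_neg, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' @export
print.leamq_validation <- function(x, ...) {
  m <- x$manifest
  cat("LEAM-Q validation pipeline\n")
  cat(sprintf("  athletes: %d (cases %d / controls %d / excluded %d)\n",
              m$n_input, m$n_cases, m$n_controls, m$n_excluded))
  cat(sprintf("  association screen: %d tests at p < %.2f, %d significant\n",
              m$n_association_tests, m$p_threshold,
              sum(!is.na(x$associations$p_value) &
                    x$associations$p_value < m$p_threshold)))
  cat(sprintf("  retained variables (sensitivity >= %.0f%%): %s\n",
              100 * m$min_sensitivity,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(none)"))
  invisible(x)
}
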