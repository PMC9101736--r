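#' Covariate-adjusted association between a clinical outcome and a
#' questionnaire predictor
#'
#' Fits a linear model for continuous clinical outcomes or a logistic
#' model for binary low/high flags, with the questionnaire variable as
#' predictor and adjustment for age, BMI, elite status and centre. Centre
#' enters as a categorical covariate only when more than one centre is
#' present among the complete-case rows actually used. Returns the Wald
#' slope, standard error and p-value for the predictor.
#'
#' Rank-deficient fits drop the aliased covariates (noted in the result);
#' logistic fits with separation are flagged rather than dropped.
#'
#' @param data a data frame containing all variables.
#' @param outcome name of the outcome column. Logical or two-level columns
#'   are fitted by logistic regression, numeric columns by linear
#'   regression.
#' @param predictor name of the questionnaire-variable column.
#' @param covariates covariate column names; missing columns are skipped.
#' @return one-row data frame: `outcome`, `predictor`, `model`, `slope`,
#'   `se`, `p_value`, `n`, `covariates`, `note`.
#' @export
fit_association <- function(data, outcome, predictor,
                            covariates = c("age", "bmi", "elite", "centre")) {
  covariates <- intersect(covariates, names(data))
  cols <- c(outcome, predictor, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  note <- character(0)

  y <- d[[outcome]]
  binary <- is.logical(y) || length(unique(y[!is.na(y)])) == 2
  empty <- data.frame(outcome = outcome, predictor = predictor,
                      model = if (binary) "logistic" else "linear",
                      slope = NA_real_, se = NA_real_, p_value = NA_real_,
                      n = nrow(d), covariates = "", note = "",
                      stringsAsFactors = FALSE)
  if (nrow(d) < length(cols) + 2 ||
      length(unique(d[[predictor]])) < 2 ||
      (binary && length(unique(y)) < 2)) {
    empty$note <- "insufficient data"
    return(empty)
  }

  if ("centre" %in% covariates) {
    if (length(unique(d$centre)) < 2) {
      covariates <- setdiff(covariates, "centre")
      note <- c(note, "centre dropped (single centre)")
    } else {
      d$centre <- factor(d$centre)
    }
  }
  ## drop constant covariates up front (aliased by the intercept)
  const <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]])) < 2, logical(1))]
  if (length(const)) {
    covariates <- setdiff(covariates, const)
    note <- c(note, paste("dropped constant covariate(s):",
                          paste(const, collapse = ", ")))
  }

  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  if (binary) {
    d[[outcome]] <- if (is.logical(y)) as.integer(d[[outcome]]) else
      as.integer(d[[outcome]] == max(y))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = d, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep) note <- c(note, "possible separation")
    model <- "logistic"
  } else {
    fit <- stats::lm(fml, data = d)
    model <- "linear"
  }

  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    keep <- setdiff(covariates, aliased)
    note <- c(note, paste("dropped aliased covariate(s):",
                          paste(aliased, collapse = ", ")))
    fml <- stats::reformulate(c(predictor, keep), response = outcome)
    fit <- if (binary)
      suppressWarnings(stats::glm(fml, data = d, family = stats::binomial()))
    else stats::lm(fml, data = d)
    covariates <- keep
  }

  sm <- summary(fit)$coefficients
  row <- sm[predictor, ]
  data.frame(outcome = outcome, predictor = predictor, model = model,
             slope = unname(row[1]), se = unname(row[2]),
             p_value = unname(row[4]), n = nrow(d),
             covariates = paste(covariates, collapse = "+"),
             note = paste(note, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Run the full association screen
#'
#' Fits [fit_association()] for every combination of clinical outcome and
#' questionnaire predictor, on complete cases per pair (the per-fit `n` is
#' reported, and so is the total number of tests performed: the screen
#' uses unadjusted p-values, so the multiple-testing burden must stay
#' visible).
#'
#' @param data merged per-athlete data.
#' @param outcomes,predictors column-name character vectors.
#' @inheritParams fit_association
#' @return data frame of association results with attribute `n_tests`.
#' @export
association_screen <- function(data, outcomes, predictors,
                               covariates = c("age", "bmi", "elite",
                                              "centre")) {
  grid <- expand.grid(outcome = outcomes, predictor = predictors,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    fit_association(data, grid$outcome[i], grid$predictor[i], covariates)))
  attr(res, "n_tests") <- sum(!is.na(res$p_value))
  res
}
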