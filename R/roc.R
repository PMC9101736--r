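#' ROC analysis with Youden-index threshold selection
#'
#' Evaluates a questionnaire score as a classifier of a binary adverse
#' clinical state under the fixed orientation "higher score = adverse".
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores (so integer-scored variables yield half-integer
#' thresholds); a positive call is `score > threshold`. The returned
#' threshold maximises Youden's `J = sensitivity + specificity - 1`, with
#' ties broken towards higher specificity and then towards the lower
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) vector; `TRUE` is the adverse class on
#'   which sensitivity is computed.
#' @param min_sensitivity retention rule: the variable is retained when
#'   sensitivity at the selected threshold is at least this value
#'   (default 0.60).
#' @return an object of class `leamq_roc`: list with `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`, `retained`, `n_pos`,
#'   `n_neg` and the full `curve` data frame over candidate thresholds.
#' @examples
#' roc_youden(c(0, 0, 1, 1, 2, 3, 3, 4), c(0, 0, 0, 1, 0, 1, 1, 1))
#' @export
roc_youden <- function(scores, labels, min_sensitivity = 0.6) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  u <- sort(unique(scores))
  if (length(u) < 2) {
    warning("all scores identical: no discrimination (J = 0)", call. = FALSE)
    curve <- data.frame(threshold = u, sensitivity = 0, specificity = 1,
                        youden_j = 0)
    return(structure(list(threshold = u, sensitivity = 0, specificity = 1,
                          youden_j = 0, retained = FALSE, n_pos = n_pos,
                          n_neg = n_neg, curve = curve),
                     class = "leamq_roc"))
  }
  thr <- (u[-1] + u[-length(u)]) / 2
  tp <- vapply(thr, function(t) sum(scores[labels] > t), numeric(1))
  tn <- vapply(thr, function(t) sum(scores[!labels] <= t), numeric(1))
  sens <- tp / n_pos
  spec <- tn / n_neg
  j <- sens + spec - 1
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, youden_j = j)
  ## max J; ties -> higher specificity, then lower threshold. Ranked on
  ## integer counts (J ordering equals that of tp*n_neg + tn*n_pos) so
  ## exact ties are not perturbed by floating-point rounding.
  best <- order(-(tp * n_neg + tn * n_pos), -tn, thr)[1]
  structure(list(threshold = thr[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best],
                 retained = sens[best] >= min_sensitivity,
                 n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "leamq_roc")
}

#' @export
print.leamq_roc <- function(x, ...) {
  cat(sprintf(
    "ROC/Youden: threshold %.2f, sensitivity %.0f%%, specificity %.0f%%, J = %.2f (%s)\n",
    x$threshold, 100 * x$sensitivity, 100 * x$specificity, x$youden_j,
    if (x$retained) "retained" else "not retained"))
  invisible(x)
}

#' Apply the minimum-sensitivity retention rule
#'
#' A screened questionnaire variable is retained when at least one of its
#' ROC analyses reaches the minimum sensitivity (default 60%) at the
#' Youden-optimal threshold. The boundary is inclusive.
#'
#' @param roc_results a data frame of ROC results with columns `predictor`
#'   and `sensitivity` (as produced by the pipeline), or a named list of
#'   `leamq_roc` objects keyed by predictor.
#' @param min_sensitivity minimum sensitivity, default 0.60.
#' @return character vector of retained predictor names.
#' @export
retain_variables <- function(roc_results, min_sensitivity = 0.6) {
  if (is.data.frame(roc_results)) {
    if (!nrow(roc_results)) return(character(0))
    keep <- roc_results$sensitivity >= min_sensitivity
    sort(unique(roc_results$predictor[keep]))
  } else {
    sens <- vapply(roc_results, function(x) x$sensitivity, numeric(1))
    sort(unique(names(sens)[sens >= min_sensitivity]))
  }
}
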