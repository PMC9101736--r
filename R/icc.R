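#' Test-retest intraclass correlation, ICC(3,1)
#'
#' Single-measure consistency ICC from the two-way mixed-effects ANOVA
#' decomposition of a subjects-by-occasions score matrix:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E)}
#' with `MS_R` the between-subject and `MS_E` the residual
#' (subject-by-occasion interaction) mean square. The consistency form is
#' insensitive to a constant shift between administrations, the usual
#' choice for 14-day test-retest of a fixed instrument. An
#' absolute-agreement variant, which charges any systematic shift between
#' occasions against reliability, is available via `type = "agreement"`.
#'
#' A 95% confidence interval is computed from the F statistic
#' `MS_R / MS_E` (Shrout-Fleiss); for the agreement form the interval is
#' approximated on the same F (reported as such).
#'
#' @param test,retest numeric score vectors, one value per subject; or
#'   pass a two-column matrix as `test`.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf_level confidence level for the interval.
#' @return an object of class `leamq_icc`: list with `icc`, `model`,
#'   `type`, `n_subjects`, `k`, `ci` (length-2), `conf_level`, and the
#'   mean squares.
#' @examples
#' set.seed(1)
#' t1 <- rnorm(40); icc_test_retest(t1, t1 + rnorm(40, sd = 0.5))
#' @export
icc_test_retest <- function(test, retest = NULL,
                            type = c("consistency", "agreement"),
                            conf_level = 0.95) {
  type <- match.arg(type)
  m <- if (is.null(retest)) as.matrix(test) else cbind(test, retest)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects with both administrations")
  G <- mean(m)
  SSR <- k * sum((rowMeans(m) - G)^2)
  SSC <- n * sum((colMeans(m) - G)^2)
  SSE <- sum((m - G)^2) - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  if (MSR <= .Machine$double.eps^0.75 * max(1, abs(G))) {
    warning("zero between-subject variance; ICC reported as 0", call. = FALSE)
    icc <- 0
    ci <- c(NA_real_, NA_real_)
  } else if (type == "consistency") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    ci <- icc_f_ci(MSR, MSE, n, k, conf_level)
  } else {
    icc <- (MSR - MSE) /
      (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
    ci <- icc_f_ci(MSR, MSE, n, k, conf_level)
  }
  structure(list(icc = icc,
                 model = "two-way mixed, single measure",
                 type = type, n_subjects = n, k = k,
                 ms = c(subjects = MSR, occasions = MSC, error = MSE),
                 ci = ci, conf_level = conf_level),
            class = "leamq_icc")
}

icc_f_ci <- function(MSR, MSE, n, k, conf_level) {
  if (MSE <= 0) return(c(1, 1))        # exact agreement
  alpha <- 1 - conf_level
  F0 <- MSR / MSE
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  FL <- F0 / stats::qf(1 - alpha / 2, df1, df2)
  FU <- F0 * stats::qf(1 - alpha / 2, df2, df1)
  c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
}

#' @export
print.leamq_icc <- function(x, ...) {
  cat(sprintf("ICC(3,1) %s = %.3f  (%d%% CI %.3f-%.3f), %s, n = %d, k = %d\n",
              x$type, x$icc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$model, x$n_subjects, x$k))
  invisible(x)
}

#' Remove unreliable items after test-retest
#'
#' Items whose test-retest ICC falls below the cutoff are dropped from
#' further analysis; removals are reported via `message()` so runs keep an
#' audit trail of the instrument revision.
#'
#' @param item_iccs named numeric vector of per-item ICCs (or a named list
#'   of `leamq_icc` objects).
#' @param cutoff minimum acceptable ICC (default 0.5).
#' @return list with `retained` and `removed` item-id character vectors
#'   and the `cutoff` used.
#' @export
drop_unreliable_items <- function(item_iccs, cutoff = 0.5) {
  if (is.list(item_iccs)) {
    item_iccs <- vapply(item_iccs, function(x)
      if (inherits(x, "leamq_icc")) x$icc else as.numeric(x), numeric(1))
  }
  if (length(item_iccs) && is.null(names(item_iccs))) {
    stop("item_iccs must be named by item_id")
  }
  removed <- names(item_iccs)[item_iccs < cutoff]
  if (length(removed)) {
    message("removing ", length(removed), " item(s) with ICC < ", cutoff,
            ": ", paste(removed, collapse = ", "))
  }
  list(retained = setdiff(names(item_iccs), removed), removed = removed,
       cutoff = cutoff)
}
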