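#' Pooled two-sample t-test from group summary statistics
#'
#' Student's pooled-variance two-sample t-test computed from printed group
#' means, standard deviations and sizes, as used for case-control
#' comparisons of questionnaire variables. With raw data whose moments
#' match the summaries, the result is identical to
#' `t.test(..., var.equal = TRUE)`.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param variable optional variable label carried into the result.
#' @return one-row data frame: `variable`, `mean1`, `sd1`, `n1`, `mean2`,
#'   `sd2`, `n2`, `t`, `df`, `p_value`, `test`.
#' @examples
#' pooled_t_from_summary(1.96, 1.93, 77, 3.00, 2.51, 38)
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                  variable = NA_character_) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) {
      t <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means: degenerate test",
              call. = FALSE)
      t <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  data.frame(variable = variable, mean1 = m1, sd1 = s1, n1 = n1,
             mean2 = m2, sd2 = s2, n2 = n2, t = t, df = df, p_value = p,
             test = "pooled two-sample t", stringsAsFactors = FALSE)
}

#' Case-control comparison of a variable from raw values
#'
#' Convenience wrapper computing group summaries from raw per-athlete
#' values and delegating to [pooled_t_from_summary()].
#'
#' @param values numeric vector.
#' @param group factor-like vector with two levels; the first level in
#'   `levels` order is group 1.
#' @param variable label for the output row.
#' @return as [pooled_t_from_summary()]; `NA` row when either group has
#'   fewer than two non-missing values.
#' @export
compare_groups <- function(values, group, variable = NA_character_) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  lv <- levels(group)
  if (length(lv) != 2 || min(table(group)) < 2) {
    return(data.frame(variable = variable, mean1 = NA_real_, sd1 = NA_real_,
                      n1 = sum(group == lv[1]), mean2 = NA_real_,
                      sd2 = NA_real_,
                      n2 = if (length(lv) > 1) sum(group == lv[2]) else 0L,
                      t = NA_real_, df = NA_real_, p_value = NA_real_,
                      test = "pooled two-sample t", stringsAsFactors = FALSE))
  }
  x1 <- values[group == lv[1]]; x2 <- values[group == lv[2]]
  pooled_t_from_summary(mean(x1), stats::sd(x1), length(x1),
                        mean(x2), stats::sd(x2), length(x2),
                        variable = variable)
}
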