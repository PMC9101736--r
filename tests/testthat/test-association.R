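test_that("an exact linear map recovers its slope with a vanishing p-value", {
  set.seed(2)
  d <- data.frame(score = rpois(40, 3))
  d$outcome <- 2 * d$score
  r <- suppressWarnings(       # lm warns on an essentially perfect fit
    fit_association(d, "outcome", "score", covariates = character(0)))
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-12)
  expect_equal(r$model, "linear")
  expect_equal(r$n, 40)
})

test_that("linear fit equals the normal-equations solution on a random instance", {
  set.seed(31)
  d <- data.frame(score = rnorm(50), age = rnorm(50, 28, 6),
                  bmi = rnorm(50, 22, 2), elite = runif(50) < 0.5)
  d$outcome <- 1.5 * d$score - 0.1 * d$age + rnorm(50)
  r <- fit_association(d, "outcome", "score",
                       covariates = c("age", "bmi", "elite"))
  X <- cbind(1, d$score, d$age, d$bmi, as.numeric(d$elite))
  beta <- solve(crossprod(X), crossprod(X, d$outcome))
  sigma2 <- sum((d$outcome - X %*% beta)^2) / (50 - 5)
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  expect_equal(r$slope, beta[2], tolerance = 1e-8)
  expect_equal(r$se, se[2], tolerance = 1e-8)
})

test_that("binary outcomes are fitted by logistic regression", {
  set.seed(5)
  d <- data.frame(score = rnorm(120))
  d$flag <- runif(120) < stats::plogis(-0.5 + 0.8 * d$score)
  r <- fit_association(d, "flag", "score", covariates = character(0))
  expect_equal(r$model, "logistic")
  fit <- stats::glm(flag ~ score, data = d, family = binomial())
  expect_equal(r$slope, unname(coef(fit)["score"]), tolerance = 1e-10)
  expect_equal(r$p_value,
               summary(fit)$coefficients["score", 4], tolerance = 1e-10)
})

test_that("centre enters only with more than one centre in the rows used", {
  set.seed(6)
  d <- data.frame(score = rnorm(60), outcome = rnorm(60),
                  centre = "oslo", age = rnorm(60, 28, 5),
                  bmi = rnorm(60, 22, 2), elite = TRUE)
  r <- fit_association(d, "outcome", "score")
  expect_false(grepl("centre", r$covariates))
  expect_match(r$note, "single centre")
  # elite constant too: dropped rather than rank-deficient
  expect_false(grepl("elite", r$covariates))
  d$centre <- rep(c("oslo", "canberra"), 30)
  r2 <- fit_association(d, "outcome", "score")
  expect_match(r2$covariates, "centre")
})

test_that("collinear covariates are dropped with a note", {
  set.seed(8)
  d <- data.frame(score = rnorm(50), age = rnorm(50, 28, 5))
  d$bmi <- d$age * 2          # aliased
  d$outcome <- d$score + rnorm(50)
  r <- fit_association(d, "outcome", "score", covariates = c("age", "bmi"))
  expect_match(r$note, "aliased")
  expect_false(is.na(r$slope))
})

test_that("the null distribution of the screen p-value is roughly uniform", {
  set.seed(13)
  ps <- replicate(200, {
    d <- data.frame(score = rpois(60, 2), outcome = rnorm(60))
    fit_association(d, "outcome", "score", covariates = character(0))$p_value
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("the screen reports its test count and per-fit n", {
  co <- generate_cohort(cohort_config(n = 60, seed = 17))
  scores <- score_responses(co$responses)
  d <- build_analysis_table(scores, co$clinical)
  res <- association_screen(d, c("t3", "total_testosterone"),
                            c("dizziness", "wellbeing"),
                            covariates = c("age", "bmi"))
  expect_equal(nrow(res), 4)
  expect_equal(attr(res, "n_tests"), sum(!is.na(res$p_value)))
  expect_true(all(res$n <= 60))
})
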