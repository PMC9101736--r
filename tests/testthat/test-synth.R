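test_that("the generator is reproducible and empty at n = 0", {
  a <- generate_cohort(cohort_config(n = 40, seed = 123))
  b <- generate_cohort(cohort_config(n = 40, seed = 123))
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_config(n = 40, seed = 124))
  expect_false(identical(a$clinical, c_$clinical))
  e <- generate_cohort(cohort_config(n = 0, seed = 1))
  expect_equal(nrow(e$responses), 0)
  expect_equal(nrow(e$clinical), 0)
})

test_that("marker marginals match their configured means and SDs", {
  cfg <- cohort_config(n = 2000, seed = 77)
  co <- generate_cohort(cfg)
  mp <- cfg$markers
  for (m in c("total_testosterone", "cortisol", "igf1", "t3", "glucose",
              "total_chol", "spine_bmd_z", "systolic_bp")) {
    v <- co$clinical[[m]]
    v <- v[!is.na(v)]
    mu <- mp$mean[mp$marker == m]; sdv <- mp$sd[mp$marker == m]
    sem <- sdv / sqrt(length(v))
    expect_lt(abs(mean(v) - mu), 3 * sem, label = paste("mean of", m))
    expect_lt(abs(sd(v) - sdv) / sdv, 0.1, label = paste("sd of", m))
  }
})

test_that("latent severity drives the calibrated markers in the right direction", {
  co <- generate_cohort(cohort_config(n = 1500, seed = 31))
  d <- merge(co$clinical, co$truth, by = "athlete_id")
  expect_lt(cor(d$severity, d$total_testosterone, use = "complete.obs"), -0.3)
  expect_lt(cor(d$severity, d$t3, use = "complete.obs"), -0.3)
  expect_gt(cor(d$severity, d$cortisol, use = "complete.obs"), 0.1)
  s <- score_responses(co$responses)
  ds <- merge(s, co$truth, by = "athlete_id")
  expect_gt(cor(ds$severity, ds$sex_drive, use = "complete.obs"), 0.2)
  ## unloaded sections stay null
  expect_lt(abs(cor(ds$severity, ds$dizziness, use = "complete.obs")), 0.08)
})

test_that("zeroed severity loadings break every marker-severity link", {
  cfg <- cohort_config(n = 1200, seed = 55)
  cfg$markers$loading[] <- 0
  cfg$item_loading[] <- 0
  co <- generate_cohort(cfg)
  d <- merge(co$clinical, co$truth, by = "athlete_id")
  expect_lt(abs(cor(d$severity, d$total_testosterone, use = "complete.obs")),
            0.09)
  s <- merge(score_responses(co$responses), co$truth, by = "athlete_id")
  expect_lt(abs(cor(s$severity, s$sex_drive, use = "complete.obs")), 0.12)
})

test_that("version structure carries the revision: sex drive and insulin are v2-only", {
  co <- generate_cohort(cohort_config(n = 300, seed = 2))
  v1 <- co$responses$version == "v1"
  expect_true(all(is.na(co$responses$s6a[v1])))
  expect_true(all(is.na(co$clinical$insulin[co$responses$version == "v1"])))
  expect_false(all(is.na(co$responses$s6a[!v1])))
})

test_that("test-retest pairs hit their reliability target", {
  d0 <- generate_test_retest(test_retest_config(n = 100, icc = 0.9999,
                                                seed = 3))
  expect_gt(icc_test_retest(d0$test, d0$retest)$icc, 0.999)
  d <- generate_test_retest(test_retest_config(n = 800, icc = 0.71, seed = 6))
  est <- icc_test_retest(d$test, d$retest)$icc
  expect_lt(abs(est - 0.71), 0.06)
  ## symmetry: swapping administrations leaves the ICC unchanged
  expect_equal(icc_test_retest(d$retest, d$test)$icc, est)
})

test_that("per-item pairs expose heterogeneous reliabilities for item removal", {
  d <- generate_test_retest(test_retest_config(n = 250, seed = 14),
                            n_items = 4, item_iccs = c(0.85, 0.85, 0.2, 0.85))
  items <- attr(d, "items")
  iccs <- vapply(split(items, items$item_id), function(x)
    icc_test_retest(x$test, x$retest)$icc, numeric(1))
  expect_message(res <- drop_unreliable_items(iccs, cutoff = 0.5), "item03")
  expect_identical(res$removed, "item03")
})

test_that("the injected sex-drive effect strengthens with sample size", {
  ps <- vapply(c(100, 300, 1000), function(n) {
    co <- generate_cohort(cohort_config(n = n, seed = 61))
    s <- merge(score_responses(co$responses), co$truth, by = "athlete_id")
    cor.test(s$severity, s$sex_drive)$p.value
  }, numeric(1))
  expect_true(all(diff(log(ps)) < 0))
})
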