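base_panel <- function(...) {
  defaults <- list(athlete_id = "a1", centre = NA_character_, age = 27,
                   height = 180, body_mass = 73, bmi = 22.5, ffm = 64,
                   body_fat_pct = 12, spine_bmd_z = 0.2, femur_bmd_z = 0.4,
                   systolic_bp = 120, diastolic_bp = 70,
                   rmr_measured = 8100, rmr_method = "metabolic_cart",
                   glucose = 5.1, insulin = 25, cortisol = 450,
                   total_testosterone = 21, shbg = 35, albumin = 43,
                   t3 = 5.5, igf1 = 30, total_chol = 4.4, ldl = 2.5,
                   hdl = 1.5, triglycerides = 0.9)
  mods <- list(...)
  defaults[names(mods)] <- mods
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

status_of <- function(panel, indicator, ref = default_reference_config()) {
  build_indicator_profile(panel, ref)[[indicator]]
}

test_that("printed cutoffs are strict: the boundary value is never low/high", {
  # fall-back cutoffs apply when no centre is configured
  expect_equal(status_of(base_panel(t3 = 3.4), "low_t3"), "met")
  expect_equal(status_of(base_panel(t3 = 3.5), "low_t3"), "not_met")
  expect_equal(status_of(base_panel(total_testosterone = 15.9, shbg = NA),
                         "low_testosterone"), "met")
  expect_equal(status_of(base_panel(total_testosterone = 16, shbg = NA),
                         "low_testosterone"), "not_met")
  expect_equal(status_of(base_panel(bmi = 18.5), "underweight"), "not_met")
  expect_equal(status_of(base_panel(bmi = 18.4), "underweight"), "met")
  expect_equal(status_of(base_panel(spine_bmd_z = -1), "low_bmd"), "not_met")
  expect_equal(status_of(base_panel(ldl = 3), "high_ldl"), "not_met")
  expect_equal(status_of(base_panel(ldl = 3.01), "high_ldl"), "met")
  expect_equal(status_of(base_panel(cortisol = 550, insulin = NA),
                         "high_cortisol_or_ratio"), "not_met")
})

test_that("either-site and and/or branches behave as disjunctions", {
  expect_equal(status_of(base_panel(spine_bmd_z = -1.2, femur_bmd_z = 0.1),
                         "low_bmd"), "met")
  expect_equal(status_of(base_panel(spine_bmd_z = NA, femur_bmd_z = -1.3),
                         "low_bmd"), "met")
  expect_equal(status_of(base_panel(spine_bmd_z = NA, femur_bmd_z = NA),
                         "low_bmd"), "missing")
  expect_equal(status_of(base_panel(systolic_bp = 118, diastolic_bp = 70),
                         "hypotension"), "not_met")
  expect_equal(status_of(base_panel(systolic_bp = 95, diastolic_bp = 58),
                         "hypotension"), "met")
  ## cortisol below 550 with the ratio unavailable: decided not_met
  expect_equal(status_of(base_panel(cortisol = 500, insulin = NA),
                         "high_cortisol_or_ratio"), "not_met")
  expect_equal(status_of(base_panel(cortisol = 560, insulin = NA),
                         "high_cortisol_or_ratio"), "met")
  expect_equal(status_of(base_panel(cortisol = 500, insulin = 10),
                         "high_cortisol_or_ratio"), "met")  # ratio 50 > 26.6
})

test_that("RMR ratio indicator uses the method-specific cutoff", {
  p <- base_panel(ffm = 60, rmr_method = "first_principles",
                  rmr_measured = 1.05 * (500 + 22 * 60) * 4.184)
  expect_equal(status_of(p, "low_rmr_ratio"), "met")        # 1.05 < 1.11
  p$rmr_method <- "metabolic_cart"
  expect_equal(status_of(p, "low_rmr_ratio"), "not_met")    # 1.05 >= 0.88
  p$rmr_method <- NA_character_
  expect_equal(status_of(p, "low_rmr_ratio"), "missing")
})

test_that("site reference ranges shift the lowest-quartile cutoffs", {
  ref <- default_reference_config()
  # oslo t3 interval (3.9, 6.7): lowest quartile boundary at 4.6
  expect_equal(status_of(base_panel(centre = "oslo", t3 = 4.5), "low_t3", ref),
               "met")
  expect_equal(status_of(base_panel(centre = "oslo", t3 = 4.6), "low_t3", ref),
               "not_met")
  expect_error(status_of(base_panel(centre = "atlantis"), "low_t3", ref),
               "atlantis", class = "leamq_config_error")
  # IGF-1 cutoff is age-banded: the same value can be low for a younger
  # athlete and normal for an older one
  bands <- ref$centres$oslo$igf1_age_bands
  cut_young <- bands$low[1] + 0.25 * (bands$high[1] - bands$low[1])
  expect_equal(status_of(base_panel(centre = "oslo", age = 30,
                                    igf1 = cut_young - 0.1),
                         "low_igf1", ref), "met")
  expect_equal(status_of(base_panel(centre = "oslo", age = 30,
                                    igf1 = cut_young),
                         "low_igf1", ref), "not_met")
  expect_equal(status_of(base_panel(centre = "oslo", age = 45,
                                    igf1 = cut_young - 0.1),
                         "low_igf1", ref), "not_met")
})

test_that("classification follows the composite case definition", {
  st <- rep("not_met", 10)
  expect_equal(classify_lea(profile_row(st))$verdict, "control")
  # two primary indicators met
  st2 <- st; st2[1:2] <- "met"
  expect_equal(classify_lea(profile_row(st2))$verdict, "case")
  # one primary + two secondary = three overall
  st3 <- st; st3[1] <- "met"; st3[5:6] <- "met"
  expect_equal(classify_lea(profile_row(st3))$verdict, "case")
  # one primary + one secondary: below both thresholds
  st4 <- st; st4[1] <- "met"; st4[5] <- "met"
  expect_equal(classify_lea(profile_row(st4))$verdict, "control")
  # three missing including a primary: excluded regardless of met counts
  st5 <- st2; st5[c(1, 5, 6)] <- "missing"; st5[2:4] <- "met"
  expect_equal(classify_lea(profile_row(st5))$verdict, "excluded")
  # three missing but none primary: still classifiable
  st6 <- st; st6[5:7] <- "missing"
  expect_equal(classify_lea(profile_row(st6))$verdict, "control")
})

test_that("flipping an indicator to met never turns a case into a control", {
  set.seed(21)
  for (i in 1:300) {
    st <- sample(c("met", "not_met", "missing"), 10, replace = TRUE)
    before <- classify_lea(profile_row(st))$verdict
    idx <- which(st == "not_met")
    if (!length(idx)) next
    st[idx[sample.int(length(idx), 1)]] <- "met"
    after <- classify_lea(profile_row(st))$verdict
    if (before == "case") expect_equal(after, "case")
  }
})

test_that("indicator counts tally the statuses", {
  co <- generate_cohort(cohort_config(n = 80, seed = 5))
  prof <- build_indicator_profile(co$clinical)
  all10 <- as.matrix(prof[, c(primary_indicators(), secondary_indicators())])
  expect_equal(prof$n_total_met, unname(rowSums(all10 == "met")))
  expect_equal(prof$n_missing, unname(rowSums(all10 == "missing")))
  expect_equal(prof$n_primary_met,
               unname(rowSums(all10[, 1:4] == "met")))
})
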