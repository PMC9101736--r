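#' Configuration for the synthetic athlete cohort
#'
#' Describes a multi-centre cohort of adult male endurance and
#' weight-sensitive sport athletes with the statistical structure the
#' validation pipeline assumes: a standard-normal latent LEA severity per
#' athlete drives correlated deviations in the endocrine markers, RMR
#' ratio, bone density and the sex-drive item codes, while every marker
#' keeps its configured marginal mean and SD. Defaults are calibrated to
#' the whole-cohort summary statistics of the clinical verification study
#' (n = 310 analysed; 183 received questionnaire version 1 and 127 the
#' revised version 2 that carries the sex-drive items; insulin was also
#' collected only with version 2). Missingness is
#' missing-completely-at-random within blocks at the per-marker rates
#' implied by the published per-variable group sizes.
#'
#' @param n number of athletes (default 310).
#' @param seed integer seed; every draw in [generate_cohort()] derives
#'   from it.
#' @param centres named probability weights over study centres; names must
#'   exist in the reference configuration used downstream.
#' @param v2_fraction fraction of athletes receiving questionnaire
#'   version 2.
#' @param elite_fraction fraction flagged as elite athletes.
#' @param markers per-marker parameter table (see
#'   [default_marker_params()]): marginal `mean` and `sd`, signed latent
#'   `loading` (correlation with severity; negative means the marker falls
#'   as severity rises) and block `missing_rate`.
#' @param item_loading,section_loading latent loadings of the ordinal
#'   questionnaire items on severity (sex-drive section only by default)
#'   and on their shared section factor.
#' @return a list of class `leamq_cohort_config`.
#' @export
cohort_config <- function(n = 310, seed = 1,
                          centres = c(canberra = 0.35, oslo = 0.25,
                                      kristiansand = 0.25,
                                      copenhagen = 0.15),
                          v2_fraction = 127 / 310,
                          elite_fraction = 0.64,
                          markers = default_marker_params(),
                          item_loading = c(sex_drive = 0.45, wellbeing = 0,
                                           dizziness = 0, gastrointestinal = 0,
                                           thermoregulation = 0,
                                           injury_illness = 0),
                          section_loading = 0.40) {
  stopifnot(n >= 0, all(centres >= 0), sum(centres) > 0,
            v2_fraction >= 0, v2_fraction <= 1,
            all(markers$sd > 0),
            all(markers$missing_rate >= 0 & markers$missing_rate <= 1),
            all(abs(markers$loading) <= 1))
  structure(list(n = n, seed = seed, centres = centres / sum(centres),
                 v2_fraction = v2_fraction, elite_fraction = elite_fraction,
                 markers = markers, item_loading = item_loading,
                 section_loading = section_loading),
            class = "leamq_cohort_config")
}

#' @rdname cohort_config
#' @export
default_marker_params <- function() {
  p <- function(marker, mean, sd, loading, missing_rate)
    data.frame(marker = marker, mean = mean, sd = sd, loading = loading,
               missing_rate = missing_rate, stringsAsFactors = FALSE)
  rbind(
    p("age", 27.9, 6.9, 0.30, 0),
    p("height", 181.6, 7.7, 0, 0),
    p("bmi", 22.2, 2.0, -0.12, 0),
    p("body_fat_pct", 11.9, 3.5, 0, 0.03),
    p("spine_bmd_z", -0.01, 1.00, -0.30, 0.16),
    p("femur_bmd_z", 0.35, 1.00, -0.25, 0.17),
    p("systolic_bp", 118.6, 10.4, -0.20, 0.20),
    p("diastolic_bp", 67.6, 7.0, -0.10, 0.20),
    ## RMR ratio is method-specific: first-principles measurements read
    ## systematically higher, so each method has its own marginal mean
    p("rmr_ratio_first_principles", 1.15, 0.12, -0.35, 0.07),
    p("rmr_ratio_metabolic_cart", 0.95, 0.12, -0.35, 0.07),
    p("total_testosterone", 19.8, 5.8, -0.55, 0.17),
    p("shbg", 33, 10, 0, 0.19),
    p("albumin", 43, 2.5, 0, 0.50),
    p("t3", 5.3, 0.8, -0.60, 0.43),
    p("igf1", 28.7, 8.5, -0.55, 0.30),
    p("cortisol", 461.5, 127.5, 0.25, 0.30),
    p("insulin", 24.2, 10.3, -0.40, 0.08),
    p("glucose", 5.0, 0.45, -0.15, 0.15),
    p("total_chol", 4.6, 0.9, 0.20, 0.22),
    p("ldl", 2.7, 0.8, 0.15, 0.23),
    p("hdl", 1.5, 0.35, 0.20, 0.23),
    p("triglycerides", 0.92, 0.35, 0, 0.22),
    p("weight_flux", 9.1, 5.5, 0.18, 0.05)
  )
}

## default per-item marginal code probabilities over codes 0..3
item_code_probs <- function(section) {
  switch(section,
         sex_drive = NULL,  # item-specific, below
         wellbeing = c(0.22, 0.28, 0.26, 0.24),
         c(0.72, 0.20, 0.06, 0.02))
}

sex_drive_probs <- list(
  s6a = c(0.32, 0.45, 0.18, 0.05),
  s6b = c(0.85, 0.10, 0.04, 0.01),
  s6c = c(0.50, 0.25, 0.13, 0.12),
  s6d = c(0.86, 0.09, 0.04, 0.01))

#' Generate a synthetic athlete cohort
#'
#' Draws questionnaire responses and a clinical panel for `config$n`
#' athletes. A latent severity `z ~ N(0,1)` is shared between the two
#' tables: marker `m` is generated as
#' `mean_m + sd_m * (loading_m * z + sqrt(1 - loading_m^2) * noise)`, so
#' its marginal mean and SD equal the configured values for any loading;
#' ordinal item codes are produced by thresholding a latent
#' `item_loading * z + section_loading * f_section + noise` at the normal
#' quantiles of the configured marginal code frequencies. Spine and femur
#' BMD Z-scores share an athlete-level bone factor. Version-2-only items
#' (sex drive) and insulin are structurally missing for version-1
#' athletes; all other missingness is MCAR at the configured block rates.
#'
#' @param config a [cohort_config()].
#' @return list with `responses` (questionnaire table, one column per
#'   item), `clinical` (clinical panel) and `truth` (athlete_id with the
#'   latent severity, for simulation studies only).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "leamq_cohort_config"))
  n <- config$n
  key <- default_scoring_key()
  if (n == 0) {
    return(list(responses = empty_response_table(key),
                clinical = empty_clinical_table(),
                truth = data.frame(athlete_id = character(0),
                                   severity = numeric(0))))
  }
  set.seed(config$seed)
  id <- sprintf("ath%04d", seq_len(n))
  z <- stats::rnorm(n)                       # latent LEA severity
  centre <- sample(names(config$centres), n, replace = TRUE,
                   prob = config$centres)
  version <- ifelse(stats::runif(n) < config$v2_fraction, "v2", "v1")
  elite <- stats::runif(n) < config$elite_fraction

  mp <- config$markers
  prm <- function(name) mp[mp$marker == name, ]
  draw <- function(name, z_vec = z, extra = NULL) {
    p <- prm(name)
    lam <- p$loading
    if (is.null(extra)) {
      lat <- lam * z_vec + sqrt(1 - lam^2) * stats::rnorm(length(z_vec))
    } else {
      ## extra: list(factor, weight) for an additional shared factor
      w <- extra$weight
      lat <- lam * z_vec + w * extra$factor +
        sqrt(max(0, 1 - lam^2 - w^2)) * stats::rnorm(length(z_vec))
    }
    p$mean + p$sd * lat
  }

  age <- pmin(pmax(round(draw("age")), 18), 50)
  height <- round(draw("height"), 1)
  bmi <- draw("bmi")
  body_mass <- round(bmi * (height / 100)^2, 1)
  bmi <- round(body_mass / (height / 100)^2, 2)
  body_fat <- pmax(draw("body_fat_pct"), 3)
  ffm <- round(body_mass * (1 - body_fat / 100), 1)

  bone <- stats::rnorm(n)                    # shared skeletal factor
  spine_z <- round(draw("spine_bmd_z", extra = list(factor = bone,
                                                    weight = 0.55)), 2)
  femur_z <- round(draw("femur_bmd_z", extra = list(factor = bone,
                                                    weight = 0.55)), 2)

  rmr_method <- ifelse(centre == "canberra", "first_principles",
                       "metabolic_cart")
  ratio <- ifelse(rmr_method == "first_principles",
                  draw("rmr_ratio_first_principles"),
                  draw("rmr_ratio_metabolic_cart"))
  ratio <- pmax(ratio, 0.5)
  rmr_measured <- round(ratio * (500 + 22 * ffm) * 4.184)   # kJ/day

  tt <- pmax(draw("total_testosterone"), 1)
  shbg <- pmax(draw("shbg"), 5)
  albumin <- round(pmax(draw("albumin"), 30), 1)
  t3 <- pmax(draw("t3"), 2)
  igf1 <- pmax(draw("igf1"), 4)
  cortisol <- pmax(draw("cortisol"), 100)
  insulin <- pmax(draw("insulin"), 3)
  glucose <- pmax(draw("glucose"), 3)
  chol <- pmax(draw("total_chol"), 2)
  ldl <- pmax(draw("ldl"), 0.5)
  hdl <- pmax(draw("hdl"), 0.5)
  tg <- pmax(draw("triglycerides"), 0.2)
  sys_bp <- round(draw("systolic_bp"))
  dia_bp <- round(draw("diastolic_bp"))

  ## questionnaire items: latent thresholding with section factors
  scored <- key[key$section != "demographics", ]
  answers <- matrix(NA_integer_, n, nrow(scored),
                    dimnames = list(NULL, scored$item_id))
  sections <- unique(scored$section)
  sec_factor <- matrix(stats::rnorm(n * length(sections)), n,
                       dimnames = list(NULL, sections))
  for (j in seq_len(nrow(scored))) {
    it <- scored[j, ]
    lam <- unname(config$item_loading[it$section])
    if (is.na(lam)) lam <- 0
    w <- config$section_loading
    u <- lam * z + w * sec_factor[, it$section] +
      sqrt(max(0, 1 - lam^2 - w^2)) * stats::rnorm(n)
    probs <- sex_drive_probs[[it$item_id]] %||% item_code_probs(it$section)
    cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
    code <- findInterval(u, cuts)
    ## reverse-coded items are stored as the athlete would answer them:
    ## adverse latent -> low raw code on a positively worded item
    if (it$reverse) code <- it$max_code - code
    answers[, it$item_id] <- code
  }
  ## structural missingness: version-1 forms lack the v2-only items
  v2_items <- scored$item_id[scored$version == "v2"]
  answers[version == "v1", v2_items] <- NA_integer_

  flux <- pmax(draw("weight_flux"), 0)
  lowest_w <- round(body_mass - 0.6 * flux, 1)
  highest_w <- round(lowest_w + flux, 1)

  miss <- function(x, name, structural_v1 = FALSE) {
    rate <- prm(name)$missing_rate
    x[stats::runif(n) < rate] <- NA
    if (structural_v1) x[version == "v1"] <- NA
    x
  }

  responses <- data.frame(athlete_id = id, version = version,
                          highest_weight_kg = miss(highest_w, "weight_flux"),
                          lowest_weight_kg = lowest_w,
                          stringsAsFactors = FALSE)
  responses$lowest_weight_kg[is.na(responses$highest_weight_kg)] <- NA
  responses <- cbind(responses, as.data.frame(answers))

  clinical <- data.frame(
    athlete_id = id, centre = centre, age = age, elite = elite,
    height = height, body_mass = body_mass, bmi = bmi,
    ffm = miss(ffm, "body_fat_pct"),
    body_fat_pct = round(miss(body_fat, "body_fat_pct"), 1),
    spine_bmd_z = miss(spine_z, "spine_bmd_z"),
    femur_bmd_z = miss(femur_z, "femur_bmd_z"),
    systolic_bp = miss(sys_bp, "systolic_bp"),
    diastolic_bp = miss(dia_bp, "systolic_bp"),
    rmr_measured = miss(rmr_measured, "rmr_ratio_first_principles"),
    rmr_method = rmr_method,
    glucose = round(miss(glucose, "glucose"), 1),
    insulin = round(miss(insulin, "insulin", structural_v1 = TRUE), 1),
    cortisol = round(miss(cortisol, "cortisol")),
    total_testosterone = round(miss(tt, "total_testosterone"), 1),
    shbg = round(miss(shbg, "shbg"), 1),
    albumin = miss(albumin, "albumin"),
    t3 = round(miss(t3, "t3"), 1),
    igf1 = round(miss(igf1, "igf1"), 1),
    total_chol = round(miss(chol, "total_chol"), 1),
    ldl = round(miss(ldl, "ldl"), 1),
    hdl = round(miss(hdl, "hdl"), 1),
    triglycerides = round(miss(tg, "total_chol"), 2),
    stringsAsFactors = FALSE)

  list(responses = responses, clinical = clinical,
       truth = data.frame(athlete_id = id, severity = z,
                          stringsAsFactors = FALSE))
}

empty_response_table <- function(key) {
  scored <- key$item_id[key$section != "demographics"]
  out <- data.frame(athlete_id = character(0), version = character(0),
                    highest_weight_kg = numeric(0),
                    lowest_weight_kg = numeric(0))
  for (s in scored) out[[s]] <- integer(0)
  out
}

empty_clinical_table <- function() {
  cols <- c("centre", "rmr_method")
  out <- data.frame(athlete_id = character(0))
  for (s in cols) out[[s]] <- character(0)
  num <- c("age", "height", "body_mass", "bmi", "ffm", "body_fat_pct",
           "spine_bmd_z", "femur_bmd_z", "systolic_bp", "diastolic_bp",
           "rmr_measured", "glucose", "insulin", "cortisol",
           "total_testosterone", "shbg", "albumin", "t3", "igf1",
           "total_chol", "ldl", "hdl", "triglycerides")
  for (s in num) out[[s]] <- numeric(0)
  out$elite <- logical(0)
  out
}

#' Configuration for synthetic test-retest data
#'
#' Two administrations of the questionnaire 14 days apart are modelled as
#' `score_ij = true_i + e_ij` with `true ~ N(mu, sd_true^2)` and occasion
#' noise `e ~ N(0, sd_noise^2)`, so the target reliability is
#' `ICC = sd_true^2 / (sd_true^2 + sd_noise^2)`.
#'
#' @param n number of subjects (default 42, the reliability sub-study
#'   size).
#' @param icc target intraclass correlation in (0, 1); default 0.71, the
#'   reliability the instrument reached after item removal.
#' @param total_sd total score SD across subjects and occasions.
#' @param mean mean total score.
#' @param seed integer seed.
#' @return list of class `leamq_retest_config`.
#' @export
test_retest_config <- function(n = 42, icc = 0.71, total_sd = 6, mean = 20,
                               seed = 1) {
  stopifnot(n >= 3, icc > 0, icc < 1, total_sd > 0)
  structure(list(n = n, icc = icc, total_sd = total_sd, mean = mean,
                 seed = seed),
            class = "leamq_retest_config")
}

#' Generate paired test-retest scores
#'
#' @param config a [test_retest_config()].
#' @param n_items optionally, also generate `n_items` per-item paired
#'   codes with heterogeneous reliabilities (`item_iccs`), for exercising
#'   unreliable-item removal.
#' @param item_iccs per-item target ICCs, recycled to `n_items`.
#' @return data frame with `subject`, `test`, `retest`; when `n_items > 0`
#'   an attribute `"items"` holds a long data frame (`subject`, `item_id`,
#'   `test`, `retest`).
#' @export
generate_test_retest <- function(config = test_retest_config(),
                                 n_items = 0, item_iccs = 0.7) {
  stopifnot(inherits(config, "leamq_retest_config"))
  set.seed(config$seed)
  sd_true <- config$total_sd * sqrt(config$icc)
  sd_noise <- config$total_sd * sqrt(1 - config$icc)
  true <- stats::rnorm(config$n, config$mean, sd_true)
  out <- data.frame(subject = sprintf("s%03d", seq_len(config$n)),
                    test = true + stats::rnorm(config$n, 0, sd_noise),
                    retest = true + stats::rnorm(config$n, 0, sd_noise))
  if (n_items > 0) {
    iccs <- rep_len(item_iccs, n_items)
    items <- do.call(rbind, lapply(seq_len(n_items), function(i) {
      ti <- stats::rnorm(config$n, 0, sqrt(iccs[i]))
      data.frame(subject = out$subject,
                 item_id = sprintf("item%02d", i),
                 test = ti + stats::rnorm(config$n, 0, sqrt(1 - iccs[i])),
                 retest = ti + stats::rnorm(config$n, 0, sqrt(1 - iccs[i])),
                 stringsAsFactors = FALSE)
    }))
    attr(out, "items") <- items
  }
  out
}
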