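test_that("all-zero response scores zero everywhere (no reverse items)", {
  key <- mini_key()
  key$reverse[] <- FALSE
  s <- score_response(list(a1 = 0, a2 = 0, a3 = 0, b1 = 0, b2 = 0, b3 = 0),
                      key, version = "v2")
  expect_identical(s$dizziness, 0)
  expect_identical(s$wellbeing, 0)
  expect_identical(s$total, 0)
})

test_that("raising any single item by one raises its section and the total by one", {
  key <- mini_key()
  base <- list(a1 = 1, a2 = 0, a3 = 2, b1 = 1, b2 = 2, b3 = 1)
  s0 <- score_response(base, key, version = "v2")
  for (id in names(base)) {
    it <- key[key$item_id == id, ]
    bumped <- base
    ## +1 after reverse adjustment: lower the raw code on reversed items
    bumped[[id]] <- base[[id]] + if (it$reverse) -1 else 1
    s1 <- score_response(bumped, key, version = "v2")
    expect_equal(s1[[it$section]], s0[[it$section]] + 1, info = id)
    expect_equal(s1$total, s0$total + 1, info = id)
  }
})

test_that("constructed two-section response matches hand summation", {
  key <- mini_key()
  key$reverse[] <- FALSE
  # codes {2,1,0} and {3,1,1}: hand sums 3 and 5, total 8
  s <- score_response(list(a1 = 2, a2 = 1, a3 = 0, b1 = 3, b2 = 1, b3 = 1),
                      key, version = "v2")
  expect_equal(s$dizziness, 3)
  expect_equal(s$wellbeing, 5)
  expect_equal(s$total, 8)
})

test_that("reverse adjustment is an involution on every allowed code", {
  key <- default_scoring_key()
  scored <- key[key$section != "demographics", ]
  for (i in seq_len(nrow(scored))) {
    codes <- 0:scored$max_code[i]
    once <- reverse_adjust(codes, scored$max_code[i], TRUE)
    expect_identical(reverse_adjust(once, scored$max_code[i], TRUE), codes)
  }
})

test_that("a fully missing section scores NA and leaves others unchanged", {
  key <- mini_key()
  full <- list(a1 = 1, a2 = 2, a3 = 0, b1 = 1, b2 = 1, b3 = 2)
  s_full <- score_response(full, key, version = "v2")
  s_part <- score_response(full[c("a1", "a2", "a3")], key, version = "v2")
  expect_true(is.na(s_part$wellbeing))
  expect_false(is.na(s_part$dizziness))
  expect_equal(s_part$dizziness, s_full$dizziness)
  expect_equal(s_part$total, s_part$dizziness)
})

test_that("unknown items and out-of-range codes are schema errors naming the item", {
  key <- mini_key()
  expect_error(score_response(list(zz9 = 1), key, version = "v2"),
               "zz9", class = "leamq_schema_error")
  expect_error(score_response(list(a1 = 7), key, version = "v2"),
               "a1", class = "leamq_schema_error")
  expect_error(score_response(list(a1 = 1.5), key, version = "v2"),
               class = "leamq_schema_error")
})

test_that("weight flux is the difference of self-reported extremes", {
  expect_equal(compute_weight_flux(80, 80), 0)
  expect_equal(compute_weight_flux(85, 75), 10)
  expect_true(is.na(compute_weight_flux(NA, 75)))
  expect_true(is.na(compute_weight_flux(85, NA)))
  expect_error(compute_weight_flux(70, 80), "swap",
               class = "leamq_schema_error")
})

test_that("low sex drive rule matches its definition on the printed examples", {
  expect_true(categorize_low_sex_drive(s6a = 2, s6c = 0, s6d = 0))
  expect_true(categorize_low_sex_drive(s6a = 1, s6c = 2, s6d = 1))
  expect_false(categorize_low_sex_drive(s6a = 1, s6c = 2, s6d = 0))
  expect_false(categorize_low_sex_drive(s6a = 0, s6c = 0, s6d = 0))
  expect_true(is.na(categorize_low_sex_drive(s6a = NA, s6c = 2, s6d = 1)))
  expect_warning(
    flag <- categorize_low_sex_drive(s6a = 2, s6c = 2, s6d = 1,
                                     version = "v1"),
    "version-1")
  expect_true(is.na(flag))
})

test_that("low sex drive flag equals brute-force evaluation over the code cross-product", {
  for (a in 0:3) for (c_ in 0:3) for (d in 0:3) {
    expected <- (a >= 2) || (c_ >= 2 && d >= 1)
    expect_identical(categorize_low_sex_drive(a, c_, d), expected,
                     info = sprintf("6A=%d 6C=%d 6D=%d", a, c_, d))
  }
})

test_that("EHMC score sums its nine items and goes missing with any constituent", {
  key <- default_scoring_key()
  ehmc_ids <- key$item_id[key$ehmc]
  expect_length(ehmc_ids, 9)
  ## post-adjustment zero: raw 0 on plain items, raw max on reversed ones
  ans <- lapply(seq_along(ehmc_ids), function(i) {
    it <- key[key$item_id == ehmc_ids[i], ]
    if (it$reverse) it$max_code else 0
  })
  names(ans) <- ehmc_ids
  expect_equal(compute_ehmc_score(ans, key), 0)

  plain <- ehmc_ids[!key$reverse[match(ehmc_ids, key$item_id)]][1]
  ans2 <- ans; ans2[[plain]] <- 2
  expect_equal(compute_ehmc_score(ans2, key), 2)

  ## hand-summation oracle on a constructed 9-item vector
  set.seed(7)
  raw <- vapply(ehmc_ids, function(id)
    sample(0:key$max_code[key$item_id == id], 1), numeric(1))
  hand <- sum(ifelse(key$reverse[match(ehmc_ids, key$item_id)],
                     key$max_code[match(ehmc_ids, key$item_id)] - raw, raw))
  expect_equal(compute_ehmc_score(as.list(raw), key), hand)

  ans3 <- ans[-1]
  expect_true(is.na(compute_ehmc_score(ans3, key)))
})

test_that("total equals the sum of section scores on random complete responses", {
  key <- default_scoring_key()
  set.seed(11)
  for (i in 1:200) {
    s <- score_response(random_answers(key), key, version = "v2")
    secs <- unlist(s[c("dizziness", "gastrointestinal", "thermoregulation",
                       "injury_illness", "wellbeing", "sex_drive")])
    expect_equal(s$total, sum(secs))
    expect_equal(s$low_sex_drive_score, s$sex_drive)
  }
})

test_that("cohort scoring agrees with single-response scoring", {
  co <- generate_cohort(cohort_config(n = 25, seed = 3))
  key <- default_scoring_key()
  scored <- score_responses(co$responses, key)
  item_cols <- intersect(names(co$responses), key$item_id)
  for (i in c(1, 7, 25)) {
    r <- co$responses[i, ]
    ans <- as.list(r[, item_cols])
    ans <- ans[!vapply(ans, is.na, logical(1))]
    one <- score_response(ans, key, version = r$version,
                          highest_weight_kg = r$highest_weight_kg,
                          lowest_weight_kg = r$lowest_weight_kg)
    for (cl in names(one)) {
      expect_equal(scored[[cl]][i], one[[cl]], info = paste(i, cl))
    }
  }
})

test_that("version-1 responses score without sex-drive composites", {
  key <- default_scoring_key()
  v1_items <- key$item_id[key$version %in% c("both", "v1") &
                            key$section != "demographics"]
  ans <- stats::setNames(as.list(rep(1, length(v1_items))), v1_items)
  s <- score_response(ans, key, version = "v1")
  expect_true(is.na(s$sex_drive))
  expect_true(is.na(s$low_sex_drive_flag))
  expect_true(is.na(s$ehmc_score))
  expect_false(is.na(s$total))
  ## answering a v2-only item on a v1 form is a schema violation
  expect_error(score_response(c(ans, list(s6a = 1)), key, version = "v1"),
               class = "leamq_schema_error")
})
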