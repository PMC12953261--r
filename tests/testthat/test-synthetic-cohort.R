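test_that("profile fixture carries the study's group parameters and validates", {
  prof <- profiles_fixture()
  expect_equal(profile_param(prof, "phq9_total", "depressed"),
               list(mean = 14.68, sd = 5.18))
  expect_equal(profile_param(prof, "who5_total", "depressed"),
               list(mean = 11.23, sd = 4.11))
  expect_equal(profile_param(prof, "bmi", "ImmunoMetabolic"),
               list(mean = 31.51, sd = 8.45))
  expect_equal(unname(prof$groups), c(491, 90))
  expect_equal(sum(prof$subtype_sizes), 90)
  expect_equal(unname(prof$subtype_sizes[c("Adaptive", "LateDepression",
                                           "ImmunoMetabolic",
                                           "OverweightNonInflammatory")]),
               c(26, 27, 9, 28))
  # categorical probabilities normalized to 1
  fin <- profile_param(prof, "financial_difficulties", "depressed")
  expect_equal(sum(fin$probs), 1, tolerance = 1e-9)
})

test_that("malformed fixtures are rejected with informative errors", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "groups: {non_depressed: 10, depressed: 5}",
    "subtype_sizes: {Adaptive: 2, LateDepression: 1, ImmunoMetabolic: 1, OverweightNonInflammatory: 1}",
    "scales: {phq9: {items: 9, min: 0, max: 3, total: phq9_total}}",
    "features:",
    "  glucose:",
    "    modality: lab",
    "    type: continuous",
    "    units: mg/dL",
    "    bounds: [40, 500]",
    "    non_depressed: {mean: 75, sd: -1}",
    "    depressed: {mean: 80, sd: 17}"
  ), bad)
  expect_error(load_profiles(bad), "negative sd", class = "depscreen_validation_error")
  expect_error(load_profiles(tempfile()), "does not exist")
})

test_that("generated cohorts have the requested deterministic composition", {
  co <- small_cohort()
  expect_equal(sum(co$diagnosis), 44)
  expect_equal(nrow(co), 220)
  expect_true(all(is.na(co$subtype[co$diagnosis == 0])))
  expect_true(all(!is.na(co$subtype[co$diagnosis == 1])))
  # identical spec => byte-identical table
  expect_identical(co, sample_cohort(generator_spec(n_total = 220, n_depressed = 44, seed = 3)))
  # spec validation
  expect_error(generator_spec(n_total = 0), class = "depscreen_argument_error")
  expect_error(generator_spec(n_total = 10, n_depressed = 11),
               class = "depscreen_argument_error")
  expect_error(sample_cohort(generator_spec(n_total = 30, n_depressed = 10,
                                            subtype = "NoSuchSubtype")),
               "unknown subtype")
})

test_that("questionnaire totals equal their item sums and items stay in bounds", {
  co <- small_cohort()
  prof <- profiles_fixture()
  for (sc in names(prof$scales)) {
    s <- prof$scales[[sc]]
    items <- as.matrix(co[, sprintf("%s_item_%d", sc, seq_len(s$items))])
    expect_true(all(rowSums(items) == co[[s$total]]), label = sc)
    expect_true(all(items >= s$min & items <= s$max), label = sc)
  }
})

test_that("large-sample group means match the calibration parameters", {
  prof <- profiles_fixture()
  n <- 4000
  co <- sample_cohort(generator_spec(n_total = 2 * n, n_depressed = n, seed = 11))
  feats <- prof$features
  cont <- feats[feats$type %in% c("continuous", "ordinal"), ]
  # restrict to features whose plausibility bounds stay > 2.5 sd away from
  # the mean, so clipping cannot move the mean measurably
  for (j in seq_len(nrow(cont))) {
    f <- cont[j, ]
    par_nd <- f$non_depressed[[1]]
    if (par_nd$sd > 0 &&
        f$lower < par_nd$mean - 2.5 * par_nd$sd &&
        f$upper > par_nd$mean + 2.5 * par_nd$sd) {
      m <- mean(co[[f$name]][co$diagnosis == 0])
      expect_lt(abs(m - par_nd$mean), 3 * par_nd$sd / sqrt(n) + 0.5 / n,
                label = sprintf("non-depressed %s", f$name))
    }
    # depressed group: subtype overrides change the mixture, so check only
    # features generated from the group-level parameters
    if (is.null(f$subtypes[[1]])) {
      par_d <- f$depressed[[1]]
      if (par_d$sd > 0 &&
          f$lower < par_d$mean - 2.5 * par_d$sd &&
          f$upper > par_d$mean + 2.5 * par_d$sd) {
        m <- mean(co[[f$name]][co$diagnosis == 1])
        expect_lt(abs(m - par_d$mean), 3 * par_d$sd / sqrt(n) + 0.5 / n,
                  label = sprintf("depressed %s", f$name))
      }
    }
  }
  # headline calibration check: depressed WHO-5 mean within 0.2 of 11.23
  expect_lt(abs(mean(co$who5_total[co$diagnosis == 1]) - 11.23), 0.2)
})

test_that("within-block correlation matches the declared exchangeable value", {
  co <- sample_cohort(generator_spec(n_total = 4000, n_depressed = 0, seed = 21))
  # same block (lab): far from their bounds, so clipping is negligible
  expect_lt(abs(cor(co$total_cholesterol, co$ldl_cholesterol) - 0.3), 0.1)
  expect_lt(abs(cor(co$hemoglobin, co$hematocrit) - 0.3), 0.1)
  # different blocks are generated independently
  expect_lt(abs(cor(co$total_cholesterol, co$systolic_bp)), 0.1)
})

test_that("item allocation partitions the total uniformly within bounds", {
  phq9 <- list(items = 9, min = 0, max = 3)
  expect_identical(allocate_item_scores(0, phq9, seed = 1), rep(0L, 9))
  expect_identical(allocate_item_scores(27, phq9, seed = 1), rep(3L, 9))
  expect_error(allocate_item_scores(5, list(items = 3, min = 2, max = 1)),
               "impossible scale")
  for (s in 1:1000) {
    it <- allocate_item_scores(14, phq9, seed = s)
    expect_identical(sum(it), 14L)
    expect_true(all(it >= 0 & it <= 3))
  }
  # totals beyond the feasible range are clipped first
  expect_identical(sum(allocate_item_scores(40, phq9, seed = 2)), 27L)
})

test_that("missingness injection is MCAR at the requested rate and spares labels", {
  co <- reference_cohort()
  expect_identical(inject_missingness(co, 0), co)
  expect_error(inject_missingness(co, 1), class = "depscreen_argument_error")
  masked <- inject_missingness(co, 0.1, seed = 5)
  feature_cols <- setdiff(names(co), c("participant_id", "diagnosis", "subtype"))
  frac <- mean(is.na(as.matrix(
    purrr::map_dfc(masked[feature_cols], as.character))))
  expect_lt(abs(frac - 0.1), 0.01)
  expect_identical(sum(is.na(masked$diagnosis)), 0L)
  expect_identical(sum(is.na(masked$participant_id)), 0L)
  # seeded reproducibility
  expect_identical(masked, inject_missingness(co, 0.1, seed = 5))
})
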