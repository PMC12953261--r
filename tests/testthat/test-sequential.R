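make_routing <- function(colour, label) {
  tibble::tibble(
    colour = factor(colour, levels = c("green", "yellow", "red")),
    label = as.integer(label)
  )
}

test_that("certainty bands partition probabilities per the band definitions", {
  b <- assign_band(c(0.70, 0.50, 0.10))
  expect_identical(as.character(b$level), c("medium", "low", "high"))
  expect_identical(as.character(b$colour), c("red", "yellow", "green"))
  # boundaries are inclusive to the upper band (on both sides of 0.5)
  edges <- assign_band(c(0.67, 0.83, 1 - 0.67, 1 - 0.83))
  expect_identical(as.character(edges$level), c("medium", "high", "medium", "high"))
  expect_identical(as.character(edges$colour), c("red", "red", "green", "green"))
  expect_error(assign_band(c(0.5, 1.2)), class = "depscreen_argument_error")
  # partition property: one colour per probability, counts add up
  p <- withr::with_seed(1, runif(500))
  bands <- assign_band(p)
  expect_identical(sum(table(bands$colour)), 500L)
  expect_true(all(bands$certainty >= 0.5 & bands$certainty <= 1))
  expect_true(all((bands$level == "low") == (bands$colour == "yellow")))
})

test_that("the stacking meta-learner respects provenance and dominance", {
  withr::with_seed(2, {
    y <- rep(c(0L, 1L), 100)
    perfect <- ifelse(y == 1, 0.95, 0.05) + rnorm(200, 0, 0.01)
  })
  oof <- cbind(m1 = perfect, m2 = perfect)
  attr(oof, "provenance") <- "out_of_fold"
  meta <- train_stacker(oof, y)
  p <- predict(meta, newdata = data.frame(m1 = perfect, m2 = perfect), type = "response")
  expect_gte(metric_triple(y, as.integer(p > 0.5))$bac, 0.98)

  # a perfect and an anti-perfect member are jointly separable
  oof2 <- cbind(m1 = perfect, m2 = 1 - perfect)
  attr(oof2, "provenance") <- "out_of_fold"
  meta2 <- train_stacker(oof2, y)
  p2 <- predict(meta2, newdata = data.frame(m1 = perfect, m2 = 1 - perfect),
                type = "response")
  expect_gte(metric_triple(y, as.integer(p2 > 0.5))$bac, 0.95)

  expect_error(train_stacker(oof[, 1, drop = FALSE], y), "two members")
  leaky <- oof
  attr(leaky, "provenance") <- "in_fold"
  expect_error(train_stacker(leaky, y), class = "depscreen_leakage_error")
  expect_error(stack_spec("clinical_15"), "two members")
})

test_that("routing honours thresholds, with exact degenerate equivalences", {
  co <- small_cohort()
  tr <- co[1:160, ]
  te <- co[161:220, ]
  ctrl <- fast_control()
  m15 <- train_base_model(modality_model_spec("clinical_15"), tr, seed = 2, control = ctrl)
  spec5 <- structure(list(name = "first5", pipeline = "P1",
                          features = top_k_features(m15, 5)),
                     class = "modality_model_spec")
  m5 <- train_base_model(spec5, tr, seed = 2, control = ctrl)

  # tau = 1 never decides early: routing equals the final model
  pol1 <- sequential_policy(1.0, step_names = c("first5", "clinical_15"))
  r1 <- route_cases(pol1, te, list(m5, m15))
  expect_identical(r1$label, predict_proba(m15, te)$label)
  expect_true(all(r1$step == 2))

  # tau = 0.5 decides everything at step one
  pol0 <- sequential_policy(0.5, step_names = c("first5", "clinical_15"))
  r0 <- route_cases(pol0, te, list(m5, m15))
  expect_identical(r0$label, predict_proba(m5, te)$label)
  expect_true(all(r0$step == 1))
  expect_equal(attr(r0, "propagated_fraction"), 0)

  # propagated fraction is monotone non-decreasing in the threshold
  fracs <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(tau) {
    r <- route_cases(sequential_policy(tau), te, list(m5, m15))
    mean(r$step > 1)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  # deciding-step fractions always account for every case
  r <- route_cases(sequential_policy(0.8), te, list(m5, m15))
  expect_equal(sum(table(r$step)) / nrow(te), 1)

  expect_error(sequential_policy(1.01), class = "depscreen_argument_error")
  expect_error(route_cases(pol1, te, list(m5)), "one fitted model per")
})

test_that("threshold tuning prefers accuracy, then fewer examinations", {
  # step-1 feature is crisp for 70% of cases and blank for the rest; the
  # step-2 feature separates everyone but with more noise, so routing the
  # confident step-1 cases early genuinely helps
  withr::with_seed(9, {
    n <- 500
    y <- rep(c(0L, 1L), n / 2)
    ambiguous <- as.logical(rbinom(n, 1, 0.3))
    f1 <- ifelse(ambiguous, rnorm(n, 0, 0.3), y * 3 + rnorm(n, 0, 0.3))
    f2 <- y * 2 + rnorm(n, 0, 0.8)
  })
  df <- tibble::tibble(diagnosis = y, f1 = f1, f2 = f2)
  spec1 <- structure(list(name = "s1", pipeline = "P1", features = "f1"),
                     class = "modality_model_spec")
  # the second step measures a different, noisier modality, so early
  # decisions on confident step-1 cases genuinely beat routing everyone on
  spec2 <- structure(list(name = "s2", pipeline = "P1", features = "f2"),
                     class = "modality_model_spec")
  tr <- df[1:350, ]
  te <- df[351:500, ]
  inner <- rep_len(1:3, 350)
  # enough boosting rounds for confident cases to saturate their scores
  ctrl <- dep_control(xgb_nrounds = 150)
  pol <- optimize_policy(list(spec1, spec2), tr, inner,
                         tau_grid = seq(0.5, 1, 0.1), control = ctrl, seed = 3)
  m1 <- train_base_model(spec1, tr, seed = 31, control = ctrl)
  m2 <- train_base_model(spec2, tr, seed = 32, control = ctrl)
  routed <- route_cases(pol, te, list(m1, m2))
  bac_routed <- metric_triple(te$diagnosis, routed$label)$bac
  bac1 <- metric_triple(te$diagnosis, predict_proba(m1, te)$label)$bac
  expect_gte(bac_routed, bac1)
  frac <- mean(routed$step > 1)
  expect_gte(frac, 0.1)
  expect_lte(frac, 0.6)
  expect_error(optimize_policy(list(spec1, spec2), tr, inner, tau_grid = numeric(0)),
               class = "depscreen_argument_error")
  expect_error(optimize_policy(list(spec1), tr, inner, tau_grid = 0.5),
               "two steps")
})

test_that("traffic-light cells count correct versus true instances", {
  routing <- make_routing(
    colour = c(rep("red", 3), rep("green", 3), rep("yellow", 2)),
    label = c(1, 1, 1, 0, 0, 0, 1, 0)
  )
  y <- c(1, 1, 0, 0, 0, 1, 1, 1)
  rep <- traffic_light_report(routing, y)
  red_dep <- rep[rep$colour == "red" & rep$class == "depressed", ]
  expect_identical(c(red_dep$correct, red_dep$total), c(2L, 2L))
  green_dep <- rep[rep$colour == "green" & rep$class == "depressed", ]
  expect_identical(c(green_dep$correct, green_dep$total), c(0L, 1L))
  # zero-case cells report an undefined percentage, not zero
  expect_true(all(is.na(rep$pct[rep$total == 0])))
  expect_false(any(rep$pct[rep$total == 0] %in% 0))
  # totals over colours account for the whole cohort
  expect_identical(sum(rep$total), length(y))
  expect_error(traffic_light_report(routing, y[-1]), "length")
})
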