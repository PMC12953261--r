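test_that("clustering consumes only biomarker modalities", {
  co <- small_cohort()
  feats <- clustering_features(co)
  dict <- cohort_dictionary(co)
  mods <- dict$modality[match(feats, dict$column)]
  expect_true(all(mods %in% c("lab", "physiological", "anthropometric")))
  expect_false(any(grepl("phq9|who5|whodas|gad7|ucla|pcptsd|lsns|madrs", feats)))
})

test_that("model selection recovers two well-separated spherical components", {
  wins <- 0
  for (s in 1:10) {
    withr::with_seed(2000 + s, {
      X <- rbind(matrix(rnorm(150 * 3), ncol = 3),
                 matrix(rnorm(150 * 3, mean = 5), ncol = 3))
    })
    sel <- select_gmm(X, k_grid = 1:4, cov_grid = c("spherical", "diag"),
                      seed = s, n_init = 3)
    if (sel$best$k == 2) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("selection criteria satisfy their identities; k = 1 has no silhouette", {
  withr::with_seed(5, X <- rbind(matrix(rnorm(80 * 2), ncol = 2),
                                 matrix(rnorm(80 * 2, 4), ncol = 2)))
  sel <- select_gmm(X, k_grid = 1:3, cov_grid = c("full", "diag"), seed = 2,
                    n_init = 3)
  cands <- sel$candidates[sel$candidates$converged, ]
  expect_true(all(abs(cands$bic - (-2 * cands$loglik + cands$df * log(nrow(X)))) < 1e-6))
  expect_true(all(abs(cands$aic - (-2 * cands$loglik + 2 * cands$df)) < 1e-6))
  k1 <- cands[cands$k == 1, ]
  expect_true(all(is.na(k1$silhouette)))
  expect_true(all(is.finite(k1$bic)))
  expect_error(select_gmm(X, cov_grid = "banana"), "unknown covariance")
  expect_error(select_gmm(X[1:5, ], k_grid = 2:8), "more rows")
})

test_that("mixture fitting is consistent, restart-monotone and recovers weights", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(300 * 2, 0), ncol = 2),
               matrix(rnorm(700 * 2, 4), ncol = 2))
  })
  sol <- fit_assign(X, k = 2, covariance = "spherical", seed = 4, n_init = 10)
  expect_equal(rowSums(sol$responsibilities), rep(1, 1000), tolerance = 1e-9)
  expect_equal(sum(sol$weights), 1, tolerance = 1e-9)
  expect_identical(sol$assignment, as.integer(apply(sol$responsibilities, 1, which.max)))
  # planted mixing weights recovered within 0.1 at n = 1000
  expect_equal(sort(sol$weights), c(0.3, 0.7), tolerance = 0.1)
  # more restarts never lose likelihood
  s1 <- fit_assign(X, k = 3, covariance = "full", seed = 4, n_init = 1)
  s20 <- fit_assign(X, k = 3, covariance = "full", seed = 4, n_init = 20)
  expect_gte(s20$loglik, s1$loglik - 1e-8)
})

test_that("cluster profiling applies the right test battery", {
  withr::with_seed(12, {
    g <- rep(1:4, each = 30)
    df <- tibble::tibble(
      normal_shift = rnorm(120) + 3 * (g == 2),   # one cluster +3 sd
      null_normal = rnorm(120),
      skewed = exp(rnorm(120)),
      cat = factor(sample(c("a", "b"), 120, replace = TRUE)),
      constant = rep(1, 120)
    )
  })
  sol <- list(assignment = g, k = 4)
  expect_warning(prof <- profile_clusters(sol, df), "constant")
  shifted <- prof[prof$variable == "normal_shift", ]
  expect_lt(shifted$p_value, 0.001)
  # the shifted cluster appears in every significant post-hoc pair
  ph <- shifted$posthoc[[1]]
  sig <- ph[ph$p_adj < 0.05, ]
  expect_true(all(sig$group1 == "2" | sig$group2 == "2"))
  expect_identical(prof$test[prof$variable == "skewed"], "kruskal")
  expect_identical(prof$test[prof$variable == "cat"], "chisq")
  expect_false("constant" %in% prof$variable)
  # eta-squared for the rank test follows (H - k + 1) / (n - k)
  kwrow <- prof[prof$test == "kruskal", ][1, ]
  expect_equal(kwrow$eta_squared,
               (kwrow$statistic - 4 + 1) / (120 - 4), tolerance = 1e-12)
})

test_that("subtype labelling follows the profile rules and degenerates safely", {
  co <- sample_cohort(generator_spec(n_total = 360, n_depressed = 360, seed = 104))
  yj <- fit_apply_yeo_johnson(co[, recovery_panel()])
  sol <- fit_assign(yj$transformed, k = 4, covariance = "diag", seed = 4, n_init = 5)
  labels <- label_clusters(sol, co)
  expect_setequal(unname(labels),
                  c("Adaptive", "LateDepression", "ImmunoMetabolic",
                    "OverweightNonInflammatory"))
  # the labelling rules are satisfied by the named clusters
  cl <- factor(sol$assignment)
  mean_by <- function(v) tapply(co[[v]], cl, mean)
  imm <- names(labels)[labels == "ImmunoMetabolic"]
  expect_identical(names(which.max(mean_by("crp"))), imm)
  expect_identical(names(which.min(mean_by("hrv_sdnn"))), imm)
  late <- names(labels)[labels == "LateDepression"]
  adap <- names(labels)[labels == "Adaptive"]
  expect_gt(mean_by("age")[late], mean_by("age")[adap])
  # the planted immuno-metabolic subtype lands mostly in its named cluster
  planted <- sol$assignment[co$subtype == "ImmunoMetabolic"]
  modal <- names(sort(table(planted), decreasing = TRUE))[1]
  expect_identical(unname(labels[modal]), "ImmunoMetabolic")

  sol3 <- list(k = 3, assignment = rep(1:3, 120))
  expect_message(expect_null(label_clusters(sol3, co)), "skipped")
  # identical clusters cannot be told apart: unresolved labels
  flat <- co
  for (v in c("crp", "hrv_sdnn", "hrv_baevskii", "bmi", "age")) flat[[v]] <- 1
  expect_warning(expect_null(label_clusters(sol, flat)), "unresolved")
})
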