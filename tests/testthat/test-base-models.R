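test_that("pipeline blueprints match their design", {
  expect_length(build_pipeline("P1")$selection_stages, 0)
  expect_identical(build_pipeline("P2")$selection_stages, "boruta")
  expect_identical(build_pipeline("P3")$selection_stages, c("boruta", "greedy"))
  p4 <- build_pipeline("P4")
  expect_identical(p4$transform, "pca")
  expect_identical(p4$classifier, "svm_linear")
  expect_error(build_pipeline("P9"), "unknown pipeline")
})

test_that("the registry reproduces the nine base models of the study table", {
  reg <- model_registry()
  expect_identical(reg$name,
                   c("somatic_metrics", "hrv", "lab", "biographic",
                     "phq15_somatic", "depression_items", "all_clinical",
                     "all_self_rated", "clinical_15"))
  expect_identical(reg$features_printed,
                   c(9L, 26L, 36L, 18L, 15L, 11L, 19L, 16L, 15L))
  expect_identical(reg$pipeline,
                   c("P1", "P4", "P4", "P2", "P3", "P3", "P3", "P3", "P1"))
  # clinical_15 is a frozen 15-item list over WHO-5 + PHQ-9 + WHODAS items,
  # flagged as derived on synthetic data, not the original instrument-study list
  c15 <- reg$features[[which(reg$name == "clinical_15")]]
  expect_length(c15, 15)
  expect_true(all(grepl("^(who5|phq9|whodas)_item_", c15)))
  expect_true(reg$synthetic_derived[reg$name == "clinical_15"])
  # every pool resolves to existing dictionary columns
  dict <- cohort_dictionary(profiles_fixture())
  expect_true(all(unlist(reg$features) %in% dict$column))
})

test_that("base models train on the training split only and predict sanely", {
  co <- small_cohort()
  spec <- modality_model_spec("clinical_15")
  fit <- train_base_model(spec, co, seed = 2, control = fast_control())
  pred <- predict_proba(fit, co)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(pred$label, as.integer(pred$probability > 0.5))
  # deeply overfit tree model: training-split BAC is near-perfect
  expect_gte(metric_triple(co$diagnosis, pred$label)$bac, 0.95)
  # duplicated case rows get identical probabilities
  dup <- co[c(1, 1, 2, 2), ]
  pd <- predict_proba(fit, dup)
  expect_identical(pd$probability[1], pd$probability[2])
  expect_identical(pd$probability[3], pd$probability[4])

  expect_error(train_base_model(spec, co[co$diagnosis == 1, ]), "single class")
  bad_spec <- structure(list(name = "x", pipeline = "P1",
                             features = c("phq9_item_1", "not_a_column")),
                        class = "modality_model_spec")
  expect_error(train_base_model(bad_spec, co), class = "depscreen_schema_error")
  expect_error(predict_proba(fit, co[, 1:4]), class = "depscreen_schema_error")
})

test_that("importance ranking and top-k selection follow the tie rules", {
  co <- small_cohort()
  fit <- train_base_model(modality_model_spec("clinical_15"), co, seed = 2,
                          control = fast_control())
  expect_true(all(fit$importance >= 0))
  allk <- top_k_features(fit, length(fit$selected))
  expect_setequal(allk, fit$selected)
  top5 <- top_k_features(fit, 5)
  expect_length(top5, 5)
  expect_true(all(top5 %in% fit$selected))
  expect_error(top_k_features(fit, 0), class = "depscreen_argument_error")
  expect_error(top_k_features(fit, 99), "exceeds")
  # deterministic tie handling: equal importances sort by name
  fake <- fit
  fake$importance[] <- 1
  expect_identical(top_k_features(fake, 3), sort(fit$selected)[1:3])
  # broom-style accessors
  expect_identical(names(tidy(fit)), c("feature", "importance"))
  expect_identical(glance(fit)$pipeline, "P1")
})

test_that("every pipeline separates a linearly separable synthetic cohort", {
  d <- make_two_group(n = 600, n_informative = 3, n_noise = 20, shift = 3, seed = 10)
  df <- tibble::as_tibble(d$X)
  df$diagnosis <- d$y
  tr <- df[1:400, ]
  te <- df[401:600, ]
  for (pid in c("P1", "P2", "P3", "P4")) {
    spec <- structure(list(name = paste0("sep_", pid), pipeline = pid,
                           features = colnames(d$X)),
                      class = "modality_model_spec")
    fit <- train_base_model(spec, tr, seed = 3, control = fast_control())
    pred <- predict_proba(fit, te)
    expect_gte(metric_triple(te$diagnosis, pred$label)$bac, 0.9)
  }
})

test_that("the PCA-SVM pipeline keeps enough components and maps importances back", {
  d <- make_two_group(n = 300, n_informative = 2, n_noise = 6, shift = 2.5, seed = 6)
  df <- tibble::as_tibble(d$X)
  df$diagnosis <- d$y
  spec <- structure(list(name = "p4", pipeline = "P4", features = colnames(d$X)),
                    class = "modality_model_spec")
  fit <- train_base_model(spec, df, seed = 1)
  pc <- fit$predictor
  expect_gte(sum(ncol(pc$rotation)), 1)
  expect_true(all(is.finite(fit$importance)))
  expect_named(fit$importance)
  # the informative features dominate the mapped-back importances
  inf_imp <- mean(fit$importance[c("inf_1", "inf_2")])
  noise_imp <- mean(fit$importance[startsWith(names(fit$importance), "noise_")])
  expect_gt(inf_imp, noise_imp)
})
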