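# thin wrappers around the boosting / SVM learners used by every pipeline

fit_xgb <- function(X, y, weights, nrounds = 300, max_depth = 3, eta = 0.1,
                    subsample = 0.8, seed = 1) {
  X <- as.matrix(X)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = weights, nthread = 1)
  withr::local_seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, subsample = subsample, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  list(booster = booster, features = colnames(X))
}

predict_xgb <- function(fit, X) {
  X <- as.matrix(X)[, fit$features, drop = FALSE]
  stats::predict(fit$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

xgb_importance <- function(fit) {
  imp <- tryCatch(xgboost::xgb.importance(model = fit$booster), error = function(e) NULL)
  out <- purrr::set_names(rep(0, length(fit$features)), fit$features)
  if (!is.null(imp) && nrow(imp) > 0) out[imp$Feature] <- imp$Gain
  out
}

#' Build a training-pipeline blueprint
#'
#' Four pipelines cover the modality-specific model designs:
#' * `P1` - gradient-boosted trees with no preprocessing or selection stage
#'   (for small feature sets);
#' * `P2` - shadow-feature (Boruta) selection, then boosting;
#' * `P3` - Boruta followed by a greedy forward stepwise wrapper, then
#'   boosting;
#' * `P4` - standardization, principal-component projection (components kept
#'   to explain at least 80% of training variance), and a linear-kernel
#'   support-vector classifier with held-in logistic probability
#'   calibration (for highly inter-correlated panels).
#'
#' @param pipeline_id One of `"P1"`, `"P2"`, `"P3"`, `"P4"`.
#' @return A `pipeline_blueprint` listing the selection stages in order.
#' @export
build_pipeline <- function(pipeline_id) {
  stages <- switch(pipeline_id,
    P1 = character(0),
    P2 = "boruta",
    P3 = c("boruta", "greedy"),
    P4 = "pca",
    abort_arg(sprintf("unknown pipeline id '%s'", pipeline_id))
  )
  structure(list(id = pipeline_id, selection_stages = setdiff(stages, "pca"),
                 transform = if (identical(stages, "pca")) "pca" else "none",
                 classifier = if (identical(stages, "pca")) "svm_linear" else "xgboost"),
            class = "pipeline_blueprint")
}

#' Training controls for the model pipelines
#'
#' Booster and selection hyperparameters are fixed rather than tuned:
#' 300 boosting rounds, depth 3, learning rate 0.1, subsample 0.8; Boruta
#' with 100 iterations at alpha 0.05 over 300 trees; greedy epsilon 0.001.
#' Reduce them for small experiments.
#'
#' @param xgb_nrounds,xgb_max_depth,xgb_eta,xgb_subsample Booster settings.
#' @param boruta_max_iter,boruta_alpha,boruta_trees Boruta settings.
#' @param greedy_epsilon,greedy_folds,greedy_nrounds Greedy wrapper settings
#'   (`greedy_nrounds` defaults to the booster rounds).
#' @param knn_k,rare_threshold Preprocessing settings.
#' @param pca_var Variance fraction retained by the P4 projection.
#' @param svm_cost Margin parameter of the P4 classifier.
#' @return A list of class `dep_control`.
#' @export
dep_control <- function(xgb_nrounds = 300, xgb_max_depth = 3, xgb_eta = 0.1,
                        xgb_subsample = 0.8,
                        boruta_max_iter = 100, boruta_alpha = 0.05,
                        boruta_trees = 300,
                        greedy_epsilon = 0.001, greedy_folds = 5,
                        greedy_nrounds = NULL,
                        knn_k = 7, rare_threshold = 0.05,
                        pca_var = 0.8, svm_cost = 1) {
  structure(as.list(environment()), class = "dep_control")
}

#' The base-model registry
#'
#' Nine modality-specific base models mirroring the study's model table:
#' name, modality description, printed feature count, pipeline id, and the
#' feature pool the pipeline selects from in the synthetic data dictionary.
#' Models whose exact engineered feature list was never published carry the
#' full modality pool and rely on the pipeline's own
#' selection stage; the `clinical_15` item list was frozen from one Boruta
#' pass over the WHO-5 + PHQ-9 + WHODAS-12 item pool on the reference
#' synthetic cohort and is marked `synthetic_derived`.
#'
#' @param path Registry YAML; defaults to the shipped registry.
#' @return A tibble with one row per base model and a `features` list-column.
#' @export
model_registry <- function(path = system.file("extdata", "model_registry.yaml",
                                              package = "depscreen", mustWork = TRUE)) {
  raw <- yaml::read_yaml(path)
  dict <- cohort_dictionary(load_profiles())
  rows <- purrr::map(raw$models, function(m) {
    feats <- resolve_feature_pool(m$features, dict)
    tibble::tibble(
      name = m$name, label = m$label, modalities = m$modalities,
      features_printed = as.integer(m$features_printed),
      pipeline = m$pipeline,
      synthetic_derived = isTRUE(m$synthetic_derived),
      features = list(feats)
    )
  })
  dplyr::bind_rows(rows)
}

# feature pools in the registry are either explicit column lists or
# selector terms: modality:<tag>, items:<scale>, total:<column>
resolve_feature_pool <- function(spec, dict) {
  out <- purrr::map(spec, function(s) {
    if (startsWith(s, "modality:")) {
      dict$column[dict$modality == sub("^modality:", "", s)]
    } else if (startsWith(s, "items:")) {
      sc <- sub("^items:", "", s)
      dict$column[grepl(sprintf("^%s_item_", sc), dict$column)]
    } else {
      if (!s %in% dict$column) abort_schema(sprintf("registry feature '%s' not in dictionary", s))
      s
    }
  })
  unique(unlist(out))
}

#' Retrieve one registry entry
#'
#' @param name Registry model name (e.g. `"clinical_15"`).
#' @param registry Registry tibble from [model_registry()].
#' @return A `modality_model_spec` list: `name`, `pipeline`, `features`.
#' @export
modality_model_spec <- function(name, registry = model_registry()) {
  row <- registry[registry$name == name, ]
  if (nrow(row) == 0) abort_arg(sprintf("unknown model '%s'", name))
  structure(list(name = row$name, label = row$label, pipeline = row$pipeline,
                 features = row$features[[1]],
                 features_printed = row$features_printed),
            class = "modality_model_spec")
}

#' Train one base model
#'
#' Fits the model's pipeline on a training split only: preprocessing
#' (rare-category aggregation, KNN imputation, one-hot encoding), the
#' pipeline's selection stages, and the classifier with the supplied
#' case weights. Importances are boosting gain for tree pipelines and
#' absolute standardized coefficients mapped back through the component
#' loadings for the PCA-SVM pipeline.
#'
#' @param spec A [modality_model_spec()] (or a list with `name`, `pipeline`,
#'   `features`).
#' @param train Training cohort rows (must contain both classes).
#' @param weights Per-case weights; defaults to class-balanced weights.
#' @param seed Integer seed.
#' @param control A [dep_control()].
#' @return A `dep_model` with the fitted plan, selected features and
#'   importances.
#' @export
train_base_model <- function(spec, train, weights = NULL, seed = 1,
                             control = dep_control()) {
  y <- check_labels(train$diagnosis)
  if (length(unique(y)) < 2) abort_arg("training split contains a single class")
  missing_feats <- setdiff(spec$features, names(train))
  if (length(missing_feats) > 0) {
    abort_schema(sprintf("missing feature column(s): %s",
                         paste(missing_feats, collapse = ", ")))
  }
  weights <- weights %||% balanced_weights(y)
  bp <- build_pipeline(spec$pipeline)

  plan <- fit_preprocess_plan(train[, spec$features, drop = FALSE],
                              rare_threshold = control$rare_threshold,
                              knn_k = control$knn_k)
  Xenc <- apply_preprocess_plan(plan, train)

  boruta <- NULL; trace <- NULL
  selected <- colnames(Xenc)
  if ("boruta" %in% bp$selection_stages && ncol(Xenc) >= 2) {
    boruta <- boruta_select(Xenc, y, max_iter = control$boruta_max_iter,
                            alpha = control$boruta_alpha,
                            seed = derive_seed(seed, "boruta"),
                            num_trees = control$boruta_trees)
    if (length(boruta$confirmed) > 0) selected <- boruta$confirmed
  }
  if ("greedy" %in% bp$selection_stages && length(selected) > 1) {
    trace <- greedy_forward_select(
      Xenc[, selected, drop = FALSE], y, candidates = selected,
      inner_folds = control$greedy_folds, epsilon = control$greedy_epsilon,
      seed = derive_seed(seed, "greedy"),
      nrounds = control$greedy_nrounds %||% control$xgb_nrounds,
      max_depth = control$xgb_max_depth, eta = control$xgb_eta,
      subsample = control$xgb_subsample
    )
    selected <- trace$selected
  }

  if (bp$classifier == "xgboost") {
    fit <- fit_xgb(Xenc[, selected, drop = FALSE], y, weights,
                   nrounds = control$xgb_nrounds, max_depth = control$xgb_max_depth,
                   eta = control$xgb_eta, subsample = control$xgb_subsample,
                   seed = derive_seed(seed, "xgb"))
    importance <- xgb_importance(fit)
    predictor <- list(kind = "xgboost", fit = fit)
  } else {
    predictor <- fit_pca_svm(Xenc, y, weights, pca_var = control$pca_var,
                             cost = control$svm_cost,
                             seed = derive_seed(seed, "svm"))
    selected <- colnames(Xenc)
    importance <- predictor$importance
  }

  structure(
    list(name = spec$name, pipeline = spec$pipeline, plan = plan,
         selected = selected, importance = importance,
         boruta = boruta, greedy = trace, predictor = predictor,
         seed = seed),
    class = "dep_model"
  )
}

fit_pca_svm <- function(X, y, weights, pca_var = 0.8, cost = 1, seed = 1) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- max(1, which(cum >= pca_var)[1])
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]

  cls_w <- c("0" = sum(weights[y == 0]) / sum(y == 0),
             "1" = sum(weights[y == 1]) / sum(y == 1))
  cls_w <- cls_w / min(cls_w)
  withr::local_seed(seed)
  svm_fit <- e1071::svm(x = scores, y = factor(y, levels = c(0, 1)),
                        kernel = "linear", cost = cost, scale = FALSE,
                        class.weights = cls_w)
  dv <- attr(stats::predict(svm_fit, scores, decision.values = TRUE),
             "decision.values")
  # orient the decision score so larger means depressed: e1071 names the
  # column "<a>/<b>" with positive values favouring class <a>
  sign_flip <- if (identical(colnames(dv)[1], "0/1")) -1 else 1
  dec <- sign_flip * as.numeric(dv)
  calib <- suppressWarnings(
    stats::glm(y ~ dec, family = stats::binomial(), weights = weights,
               data = data.frame(y = y, dec = dec))
  )
  # SVM weight vector in PC space -> back through loadings to features
  wvec <- crossprod(svm_fit$coefs, svm_fit$SV)[1, ] * sign_flip
  beta_feat <- pc$rotation[, seq_len(ncomp), drop = FALSE] %*% wvec / scale
  importance <- abs(purrr::set_names(as.numeric(beta_feat), colnames(X)))

  list(kind = "pca_svm", center = center, scale = scale,
       rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
       svm = svm_fit, sign_flip = sign_flip, calibration = calib,
       importance = importance)
}

predict_pca_svm <- function(predictor, X) {
  Xs <- sweep(sweep(X, 2, predictor$center), 2, predictor$scale, `/`)
  scores <- Xs %*% predictor$rotation
  dec <- predictor$sign_flip *
    as.numeric(attr(stats::predict(predictor$svm, scores, decision.values = TRUE),
                    "decision.values"))
  as.numeric(stats::predict(predictor$calibration,
                            newdata = data.frame(dec = dec), type = "response"))
}

#' Predict depression probabilities
#'
#' Applies the model's fitted preprocessing plan and classifier. The hard
#' label is 1 when the probability exceeds 0.5 (an exact tie predicts
#' non-depressed).
#'
#' @param model A `dep_model`.
#' @param cases Cohort rows with the model's raw input features.
#' @return A tibble: `participant_id` (if present), `probability`, `label`.
#' @export
predict_proba <- function(model, cases) {
  Xenc <- apply_preprocess_plan(model$plan, cases)
  prob <- if (model$predictor$kind == "xgboost") {
    predict_xgb(model$predictor$fit, Xenc[, model$selected, drop = FALSE])
  } else {
    predict_pca_svm(model$predictor, Xenc)
  }
  prob <- pmin(pmax(prob, 0), 1)
  tibble::tibble(
    participant_id = if ("participant_id" %in% names(cases)) cases$participant_id
                     else sprintf("case_%d", seq_len(nrow(cases))),
    probability = prob,
    label = as.integer(prob > 0.5)
  )
}

#' Top-k features by importance
#'
#' @param model A `dep_model`.
#' @param k How many features (ties broken by feature name, ascending).
#' @return Character vector of length `k`.
#' @export
top_k_features <- function(model, k) {
  if (k <= 0) abort_arg("`k` must be positive")
  imp <- model$importance[model$selected]
  if (k > length(imp)) abort_arg(sprintf("`k` = %d exceeds the %d selected features", k, length(imp)))
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}

#' @export
print.dep_model <- function(x, ...) {
  cat(sprintf("<dep_model> %s [%s], %d selected feature(s)\n",
              x$name, x$pipeline, length(x$selected)))
  invisible(x)
}

#' Tidy and glance methods
#'
#' `tidy()` returns per-unit detail (feature importances, fold metrics,
#' cluster assignments); `glance()` returns a one-row model summary.
#'
#' @param x A fitted depscreen object.
#' @param ... Unused.
#' @name tidy_depscreen
NULL

#' @rdname tidy_depscreen
#' @method tidy dep_model
#' @export
tidy.dep_model <- function(x, ...) {
  tibble::tibble(
    feature = names(x$importance),
    importance = as.numeric(x$importance)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
}

#' @rdname tidy_depscreen
#' @method glance dep_model
#' @export
glance.dep_model <- function(x, ...) {
  tibble::tibble(
    name = x$name, pipeline = x$pipeline,
    n_selected = length(x$selected), seed = x$seed
  )
}
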