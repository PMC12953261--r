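# stratified fold ids: per class, shuffled indices dealt round-robin
stratified_fold_ids <- function(y, k, seed = 1) {
  withr::local_seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Build a nested cross-validation fold plan
#'
#' Five stratified outer folds; within each outer training split, five
#' stratified inner folds for selection and threshold tuning. Assignment is
#' deterministic per seed.
#'
#' @param labels 0/1 diagnosis labels.
#' @param seed Integer seed.
#' @param k_outer,k_inner Fold counts (default 5/5).
#' @return A `fold_plan`: `outer` (fold id per case) and `inner` (list of
#'   inner fold ids over each outer-training split, `NA` for held-out
#'   cases).
#' @export
make_fold_plan <- function(labels, seed = 1, k_outer = 5, k_inner = 5) {
  y <- check_labels(labels)
  min_class <- min(table(y))
  need <- 2L * k_outer
  if (min_class < need) {
    abort_arg(sprintf(
      "smallest class has %d cases; at least %d are required for %d stratified outer folds",
      min_class, need, k_outer))
  }
  outer <- stratified_fold_ids(y, k_outer, seed = derive_seed(seed, "outer"))
  inner <- purrr::map(seq_len(k_outer), function(f) {
    ids <- rep(NA_integer_, length(y))
    tr <- which(outer != f)
    ids[tr] <- stratified_fold_ids(y[tr], k_inner,
                                   seed = derive_seed(seed, paste0("inner", f)))
    ids
  })
  structure(list(outer = outer, inner = inner, k_outer = k_outer,
                 k_inner = k_inner, seed = seed),
            class = "fold_plan")
}

#' Class-balanced case weights
#'
#' Weight for class `c` is `n_total / (2 * n_c)`, so both classes carry
#' equal total weight.
#'
#' @param labels 0/1 labels, both classes present.
#' @return Numeric weight per case.
#' @export
balanced_weights <- function(labels) {
  y <- check_labels(labels)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) abort_arg("both classes must be present")
  n <- length(y)
  w <- n / (2 * tab)
  as.numeric(w[as.character(y)])
}

#' Classification metrics with depression as the positive class
#'
#' @param y_true,y_pred 0/1 vectors of equal length; `y_true` must contain
#'   both classes.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `bac` (balanced accuracy, the mean of sensitivity and
#'   specificity).
#' @export
#' @examples
#' metric_triple(c(1, 1, 0, 0), c(1, 0, 0, 0))
metric_triple <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, "y_true")
  y_pred <- check_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) abort_arg("length mismatch")
  if (length(unique(y_true)) < 2) abort_arg("`y_true` must contain both classes")
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 bac = (sens + spec) / 2)
}

#' Balanced accuracy from a sensitivity/specificity pair
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return Their arithmetic mean.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Nested cross-validated evaluation
#'
#' For every outer fold, all fitting — imputation, selection, classifier
#' training and any inner-loop tuning — runs strictly on the outer-training
#' split; the outer-test split is predicted exactly once. The report exposes
#' a leakage check: the hash of the outer-test rows taken before and after
#' each fold's fitting.
#'
#' @param spec A [modality_model_spec()], [stack_spec()] or
#'   [sequential_spec()].
#' @param cohort Cohort tibble.
#' @param plan A [make_fold_plan()] built from `cohort$diagnosis`.
#' @param control A [dep_control()].
#' @param seed Integer seed for model fitting.
#' @return A `cv_report`: per-fold metrics, their unweighted mean, and (for
#'   sequential specs) routing results pooled over outer-test splits.
#' @export
evaluate_nested <- function(spec, cohort, plan, control = dep_control(), seed = 1) {
  stopifnot(inherits(plan, "fold_plan"))
  y <- check_labels(cohort$diagnosis)
  if (length(y) != length(plan$outer)) abort_arg("fold plan does not match cohort size")

  fold_rows <- list()
  routing_all <- list()
  hashes <- list()
  for (f in seq_len(plan$k_outer)) {
    test_idx <- which(plan$outer == f)
    train_idx <- which(plan$outer != f)
    test_rows <- cohort[test_idx, ]
    hash_before <- rlang::hash(test_rows)

    fitted <- fit_composite(spec, cohort[train_idx, ],
                            inner_ids = plan$inner[[f]][train_idx],
                            control = control,
                            seed = derive_seed(seed, paste0("fold", f)))
    pred <- predict_composite(fitted, test_rows)

    hash_after <- rlang::hash(cohort[test_idx, ])
    hashes[[f]] <- list(before = hash_before, after = hash_after)

    m <- metric_triple(y[test_idx], pred$label)
    m$fold <- f
    if (!is.null(pred$routing)) {
      r <- pred$routing
      r$fold <- f
      routing_all[[f]] <- r
      m$propagated_fraction <- mean(r$step > 1)
    }
    fold_rows[[f]] <- m
  }

  folds <- dplyr::bind_rows(fold_rows)
  mean_row <- folds |>
    dplyr::summarise(dplyr::across(c("sensitivity", "specificity", "bac",
                                     dplyr::any_of("propagated_fraction")), mean))
  structure(
    list(name = spec$name %||% class(spec)[1], folds = folds, mean = mean_row,
         routing = if (length(routing_all) > 0) dplyr::bind_rows(routing_all),
         leakage_hashes = hashes, seed = seed, plan_seed = plan$seed),
    class = "cv_report"
  )
}

# dispatch: fit/predict for base specs, stacks and sequential policies
fit_composite <- function(spec, train, inner_ids, control, seed) {
  if (inherits(spec, "stack_spec")) {
    fit_stack(spec, train, inner_ids, control, seed)
  } else if (inherits(spec, "sequential_spec")) {
    fit_sequential(spec, train, inner_ids, control, seed)
  } else {
    list(kind = "base", model = train_base_model(spec, train, seed = seed,
                                                 control = control))
  }
}

predict_composite <- function(fitted, cases) {
  if (fitted$kind == "base") {
    p <- predict_proba(fitted$model, cases)
    list(probability = p$probability, label = p$label, routing = NULL)
  } else if (fitted$kind == "stack") {
    p <- predict_stack(fitted, cases)
    list(probability = p, label = as.integer(p > 0.5), routing = NULL)
  } else {
    r <- route_cases(fitted$policy, cases, fitted$models)
    list(probability = r$probability, label = r$label, routing = r)
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean BAC %.3f (sens %.3f, spec %.3f) over %d folds\n",
              x$name, x$mean$bac, x$mean$sensitivity, x$mean$specificity,
              nrow(x$folds)))
  invisible(x)
}

#' @rdname tidy_depscreen
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::relocate(x$folds, "fold")
}

#' @rdname tidy_depscreen
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(name = x$name), x$mean,
                   tibble::tibble(seed = x$seed))
}

#' PHQ-9 cutoff screening baseline
#'
#' Screens positive when the PHQ-9 total strictly exceeds `cutoff`
#' (default 8) and scores the screen against the diagnosis label on the full
#' cohort.
#'
#' @param cohort Cohort with `phq9_total` and `diagnosis`.
#' @param cutoff Screening cutoff (positive iff total > cutoff).
#' @return A [metric_triple()] row.
#' @export
phq9_cutoff_baseline <- function(cohort, cutoff = 8) {
  tot <- cohort$phq9_total
  if (anyNA(tot)) {
    abort_arg(sprintf("missing PHQ-9 totals for case(s): %s",
                      paste(which(is.na(tot)), collapse = ", ")))
  }
  metric_triple(cohort$diagnosis, as.integer(tot > cutoff))
}
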