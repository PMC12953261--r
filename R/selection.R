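#' All-relevant feature selection with shadow features
#'
#' Each iteration appends a row-shuffled "shadow" copy of every feature,
#' fits a tree-ensemble importance model (out-of-bag permutation
#' importance) with class-balanced case weights, and scores a hit for every
#' real feature whose importance beats the best shadow. After `max_iter` iterations features are confirmed or rejected by
#' a two-sided binomial test on the hit count at level `alpha` with
#' Bonferroni correction over features; features still undecided are
#' resolved by comparing their median importance with the median of the
#' per-iteration shadow maxima.
#'
#' @param X Numeric feature matrix or data frame (>= 2 columns).
#' @param y 0/1 labels (both classes present).
#' @param max_iter Number of shadow iterations (>= 20, default 100).
#' @param alpha Significance level of the binomial decision rule.
#' @param seed Integer seed.
#' @param num_trees Trees in the importance ensemble (default 300).
#' @return A `boruta_result`: `confirmed`, `rejected`, `tentative` (feature
#'   name sets partitioning the input), `hits`, `iterations`, and the
#'   importance history.
#' @export
boruta_select <- function(X, y, max_iter = 100, alpha = 0.05, seed = 1,
                          num_trees = 300) {
  X <- as.matrix(X)
  y <- check_labels(y)
  if (ncol(X) < 2) abort_arg("need at least two features")
  if (length(unique(y)) < 2) abort_arg("labels are constant")
  if (max_iter < 20) abort_arg("`max_iter` must be >= 20")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- ncol(X)
  n <- nrow(X)
  w <- balanced_weights(y)

  withr::local_seed(seed)
  hits <- integer(p)
  imp_hist <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, colnames(X)))
  shadow_max <- numeric(max_iter)
  yf <- factor(y, levels = c(0, 1))
  for (it in seq_len(max_iter)) {
    shadow <- apply(X, 2, function(col) col[sample.int(n)])
    colnames(shadow) <- paste0(".shadow.", colnames(X))
    df <- as.data.frame(cbind(X, shadow))
    df$.y <- yf
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = num_trees, importance = "permutation",
      case.weights = w, classification = TRUE,
      num.threads = 1, seed = sample.int(.Machine$integer.max, 1)
    )
    imp <- fit$variable.importance
    real <- imp[colnames(X)]
    sh_max <- max(imp[startsWith(names(imp), ".shadow.")])
    hits <- hits + (real > sh_max)
    imp_hist[it, ] <- real
    shadow_max[it] <- sh_max
  }

  pvals <- vapply(hits, function(h) {
    stats::binom.test(h, max_iter, p = 0.5, alternative = "two.sided")$p.value
  }, numeric(1))
  padj <- pmin(pvals * p, 1)
  status <- rep("tentative", p)
  status[padj < alpha & hits > max_iter / 2] <- "confirmed"
  status[padj < alpha & hits < max_iter / 2] <- "rejected"
  # resolve leftovers: median importance vs median of the shadow maxima
  tent <- which(status == "tentative")
  if (length(tent) > 0) {
    med_shadow <- stats::median(shadow_max)
    med_imp <- apply(imp_hist[, tent, drop = FALSE], 2, stats::median)
    status[tent] <- ifelse(med_imp > med_shadow, "confirmed", "rejected")
  }

  structure(
    list(
      confirmed = colnames(X)[status == "confirmed"],
      rejected = colnames(X)[status == "rejected"],
      tentative = character(0),
      undecided_before_resolution = colnames(X)[seq_len(p) %in% tent],
      hits = purrr::set_names(hits, colnames(X)),
      iterations = max_iter,
      importance_history = imp_hist,
      shadow_max = shadow_max,
      alpha = alpha
    ),
    class = "boruta_result"
  )
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d confirmed / %d rejected after %d iterations\n",
              length(x$confirmed), length(x$rejected), x$iterations))
  if (length(x$confirmed) > 0) cat("  confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy_depscreen
#' @method tidy boruta_result
#' @export
tidy.boruta_result <- function(x, ...) {
  tibble::tibble(
    feature = names(x$hits),
    hits = as.integer(x$hits),
    iterations = x$iterations,
    median_importance = apply(x$importance_history, 2, stats::median),
    decision = dplyr::case_when(
      feature %in% x$confirmed ~ "confirmed",
      TRUE ~ "rejected"
    )
  )
}

#' Greedy forward stepwise feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximizes inner-cross-validated balanced accuracy of a gradient-boosted
#' tree classifier (class-balanced weights), breaking ties by the lower
#' candidate index, and stops at the first step whose best improvement falls
#' below `epsilon`. The final set is never empty.
#'
#' @param X Numeric feature matrix or data frame.
#' @param y 0/1 labels.
#' @param candidates Candidate feature names (default: all columns).
#' @param inner_folds Number of stratified CV folds (>= 2, default 5).
#' @param epsilon Minimum balanced-accuracy improvement to continue
#'   (default 0.001).
#' @param seed Integer seed (controls fold assignment and booster
#'   subsampling).
#' @param nrounds,max_depth,eta,subsample Booster hyperparameters.
#' @return A `greedy_trace`: `selected` (ordered), `scores` (inner-CV BAC
#'   after each addition), `stopping_reason`.
#' @export
greedy_forward_select <- function(X, y, candidates = NULL, inner_folds = 5,
                                  epsilon = 0.001, seed = 1,
                                  nrounds = 300, max_depth = 3, eta = 0.1,
                                  subsample = 0.8) {
  X <- as.matrix(X)
  y <- check_labels(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  candidates <- candidates %||% colnames(X)
  if (length(candidates) == 0) abort_arg("candidate set is empty")
  if (inner_folds < 2) abort_arg("`inner_folds` must be >= 2")
  if (min(table(y)) < inner_folds) {
    abort_arg(sprintf("cannot stratify %d folds with class counts %s",
                      inner_folds, paste(table(y), collapse = "/")))
  }

  folds <- stratified_fold_ids(y, inner_folds, seed = derive_seed(seed, "greedy_folds"))
  score_subset <- function(feats) {
    bacs <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      fit <- fit_xgb(X[tr, feats, drop = FALSE], y[tr], balanced_weights(y[tr]),
                     nrounds = nrounds, max_depth = max_depth, eta = eta,
                     subsample = subsample, seed = derive_seed(seed, paste0("gf", f)))
      p <- predict_xgb(fit, X[!tr, feats, drop = FALSE])
      metric_triple(y[!tr], as.integer(p > 0.5))$bac
    }, numeric(1))
    mean(bacs)
  }

  selected <- character(0)
  scores <- numeric(0)
  best_prev <- -Inf
  reason <- "candidates exhausted"
  remaining <- candidates
  while (length(remaining) > 0) {
    cand_scores <- vapply(remaining, function(f) score_subset(c(selected, f)), numeric(1))
    best_i <- which(cand_scores == max(cand_scores))[1]  # tie -> lower index
    improvement <- cand_scores[best_i] - best_prev
    if (length(selected) > 0 && improvement < epsilon) {
      reason <- sprintf("improvement %.4g below epsilon", improvement)
      break
    }
    selected <- c(selected, remaining[best_i])
    scores <- c(scores, cand_scores[best_i])
    best_prev <- cand_scores[best_i]
    remaining <- remaining[-best_i]
  }
  structure(
    list(selected = selected, scores = purrr::set_names(scores, selected),
         stopping_reason = reason, inner_folds = inner_folds,
         epsilon = epsilon, seed = seed,
         params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                       subsample = subsample)),
    class = "greedy_trace"
  )
}

#' @export
print.greedy_trace <- function(x, ...) {
  cat(sprintf("<greedy_trace> %d feature(s): %s\n", length(x$selected),
              paste(sprintf("%s (%.3f)", x$selected, x$scores), collapse = " -> ")))
  cat("  stopped:", x$stopping_reason, "\n")
  invisible(x)
}

#' Export a selection result to JSON
#'
#' @param boruta A `boruta_result` or `NULL`.
#' @param trace A `greedy_trace` or `NULL`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
selection_to_json <- function(boruta = NULL, trace = NULL, path) {
  jsonlite::write_json(
    list(
      confirmed = boruta$confirmed, rejected = boruta$rejected,
      hits = as.list(boruta$hits %||% list()),
      trace = if (!is.null(trace)) {
        list(selected = trace$selected, scores = as.list(trace$scores),
             stopping_reason = trace$stopping_reason)
      }
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
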