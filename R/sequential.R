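#' Specify a stacked model
#'
#' A logistic-regression meta-learner over the out-of-fold probabilities of
#' two or more member base models.
#'
#' @param members Registry names of the member base models (>= 2).
#' @param name Report name.
#' @param registry Registry tibble.
#' @return A `stack_spec`.
#' @export
stack_spec <- function(members, name = "stacked", registry = model_registry()) {
  if (length(members) < 2) abort_validation("a stack needs at least two members")
  specs <- purrr::map(members, modality_model_spec, registry = registry)
  structure(list(name = name, members = purrr::set_names(specs, members)),
            class = "stack_spec")
}

#' Train the stacking meta-learner
#'
#' Fits a class-balance-weighted logistic regression on member
#' probabilities. The probability matrix must be out-of-fold: every row's
#' member probabilities come from models not fitted on that row. The matrix
#' carries this as its `"provenance"` attribute; `"in_fold"` provenance is
#' rejected as leakage.
#'
#' @param member_probs Numeric matrix (cases x members) of out-of-fold
#'   probabilities.
#' @param labels 0/1 labels aligned to the rows.
#' @return A fitted `glm` meta-model.
#' @export
train_stacker <- function(member_probs, labels) {
  member_probs <- as.matrix(member_probs)
  if (ncol(member_probs) < 2) abort_validation("a stack needs at least two members")
  prov <- attr(member_probs, "provenance")
  if (identical(prov, "in_fold")) {
    rlang::abort("member probabilities are in-fold; the meta-learner requires out-of-fold scores",
                 class = "depscreen_leakage_error")
  }
  y <- check_labels(labels)
  df <- as.data.frame(member_probs)
  names(df) <- paste0("m", seq_len(ncol(member_probs)))
  df$.y <- y
  suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = df,
               weights = balanced_weights(y))
  )
}

fit_stack <- function(spec, train, inner_ids, control, seed) {
  y <- check_labels(train$diagnosis)
  k <- max(inner_ids, na.rm = TRUE)
  oof <- matrix(NA_real_, nrow(train), length(spec$members),
                dimnames = list(NULL, names(spec$members)))
  for (g in seq_len(k)) {
    tr <- which(inner_ids != g)
    te <- which(inner_ids == g)
    for (m in names(spec$members)) {
      fit <- train_base_model(spec$members[[m]], train[tr, ], seed = derive_seed(seed, paste0(m, g)),
                              control = control)
      oof[te, m] <- predict_proba(fit, train[te, ])$probability
    }
  }
  attr(oof, "provenance") <- "out_of_fold"
  meta <- train_stacker(oof, y)
  members <- purrr::imap(spec$members, function(s, m) {
    train_base_model(s, train, seed = derive_seed(seed, paste0(m, "full")),
                     control = control)
  })
  list(kind = "stack", members = members, meta = meta, oof = oof)
}

predict_stack <- function(fitted, cases) {
  probs <- vapply(fitted$members, function(m) predict_proba(m, cases)$probability,
                  numeric(nrow(cases)))
  df <- as.data.frame(matrix(probs, nrow(cases)))
  names(df) <- paste0("m", seq_len(ncol(df)))
  as.numeric(stats::predict(fitted$meta, newdata = df, type = "response"))
}

#' Certainty bands and traffic-light colours
#'
#' Certainty is `max(p, 1 - p)`. Bands: low certainty `[0.50, 0.67)`,
#' medium `[0.67, 0.83)`, high `[0.83, 1]` (the printed integer ranges
#' 50-66 / 67-82 / 83-100 read as displayed roundings of these half-open
#' intervals). Low certainty renders yellow; otherwise the light is red for
#' a predicted depression (`p > 0.5`) and green for a predicted
#' non-depression.
#'
#' @param p Probability vector in `[0, 1]`.
#' @return A tibble: `probability`, `certainty`, `level`
#'   (low/medium/high), `colour` (yellow/red/green).
#' @export
#' @examples
#' assign_band(c(0.10, 0.50, 0.70))
assign_band <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort_arg("probabilities must lie in [0, 1]")
  certainty <- pmax(p, 1 - p)
  level <- dplyr::case_when(
    certainty >= 0.83 ~ "high",
    certainty >= 0.67 ~ "medium",
    TRUE ~ "low"
  )
  colour <- dplyr::if_else(level == "low", "yellow",
                           dplyr::if_else(p > 0.5, "red", "green"))
  tibble::tibble(probability = p, certainty = certainty,
                 level = factor(level, levels = c("low", "medium", "high")),
                 colour = factor(colour, levels = c("green", "yellow", "red")))
}

#' Specify a sequential (propagation-threshold) model
#'
#' The default follows the study design: train the full questionnaire model
#' (`base`), split its `first_k` most important items into a first step, and
#' keep the full model as the second step; a case is decided at the first
#' step when its prediction certainty reaches the step's propagation
#' threshold, otherwise it is propagated to the richer step. Thresholds are
#' tuned on inner cross-validation to maximize mean balanced accuracy, with
#' ties broken by the smaller propagated fraction and then the smaller
#' threshold. An optional biomarker stage can be appended as a third step;
#' it is disabled by default.
#'
#' @param base Registry name of the full model (default `"clinical_15"`).
#' @param first_k Number of top-importance items in the first step.
#' @param tau_grid Candidate propagation thresholds within `[0.5, 1]`
#'   (1 never decides early).
#' @param extra_steps Optional registry names appended after the base step.
#' @param name Report name.
#' @param registry Registry tibble.
#' @return A `sequential_spec`.
#' @export
sequential_spec <- function(base = "clinical_15", first_k = 5,
                            tau_grid = seq(0.5, 1, by = 0.05),
                            extra_steps = character(0),
                            name = paste0("sequential_", base),
                            registry = model_registry()) {
  if (any(tau_grid < 0.5 | tau_grid > 1)) abort_arg("`tau_grid` must lie within [0.5, 1]")
  if (length(tau_grid) == 0) abort_arg("`tau_grid` is empty")
  structure(
    list(name = name, base = modality_model_spec(base, registry),
         first_k = first_k, tau_grid = sort(unique(tau_grid)),
         extra_steps = purrr::map(extra_steps, modality_model_spec, registry = registry)),
    class = "sequential_spec"
  )
}

#' A sequential routing policy
#'
#' @param taus Propagation threshold per non-final step, each in `[0.5, 1]`
#'   (a threshold of 1 always propagates).
#' @param step_names Names for all steps (one more than `length(taus)`).
#' @param band_edges Certainty band edges, fixed at (0.50, 0.67, 0.83).
#' @return A `sequential_policy`.
#' @export
sequential_policy <- function(taus, step_names = NULL,
                              band_edges = c(0.5, 0.67, 0.83)) {
  if (any(taus < 0.5 | taus > 1)) abort_arg("propagation thresholds must lie in [0.5, 1]")
  step_names <- step_names %||% paste0("step", seq_len(length(taus) + 1))
  if (length(step_names) != length(taus) + 1) {
    abort_arg("need one step name per threshold plus the final step")
  }
  structure(list(taus = taus, step_names = step_names, band_edges = band_edges),
            class = "sequential_policy")
}

#' Route cases through a sequential policy
#'
#' Each case is decided at the first step whose prediction certainty
#' reaches that step's propagation threshold (a threshold of 1 never
#' decides early); the final step decides every remaining case.
#'
#' @param policy A [sequential_policy()].
#' @param cases Cohort rows.
#' @param models List of fitted `dep_model`s aligned with the policy steps.
#' @return A `routing_result` tibble: `participant_id`, `step` (deciding
#'   step index), `probability`, `certainty`, `level`, `colour`, `label`;
#'   the per-step propagated fractions are attached as the
#'   `"propagated_fraction"` attribute.
#' @export
route_cases <- function(policy, cases, models) {
  stopifnot(inherits(policy, "sequential_policy"))
  n_steps <- length(policy$step_names)
  if (length(models) != n_steps) abort_arg("one fitted model per policy step is required")
  n <- nrow(cases)
  prob <- rep(NA_real_, n)
  step_of <- rep(NA_integer_, n)
  undecided <- rep(TRUE, n)
  propagated <- numeric(n_steps - 1)
  for (s in seq_len(n_steps)) {
    idx <- which(undecided)
    if (length(idx) == 0) break
    p_s <- predict_proba(models[[s]], cases[idx, , drop = FALSE])$probability
    if (s < n_steps) {
      tau <- policy$taus[s]
      decide <- if (tau >= 1) rep(FALSE, length(idx)) else pmax(p_s, 1 - p_s) >= tau
    } else {
      decide <- rep(TRUE, length(idx))
    }
    prob[idx[decide]] <- p_s[decide]
    step_of[idx[decide]] <- s
    undecided[idx[decide]] <- FALSE
    if (s < n_steps) propagated[s] <- sum(undecided) / n
  }
  bands <- assign_band(prob)
  out <- tibble::tibble(
    participant_id = if ("participant_id" %in% names(cases)) cases$participant_id
                     else sprintf("case_%d", seq_len(n)),
    step = step_of,
    probability = prob,
    certainty = bands$certainty,
    level = bands$level,
    colour = bands$colour,
    label = as.integer(prob > 0.5)
  )
  attr(out, "propagated_fraction") <- propagated
  class(out) <- c("routing_result", class(out))
  out
}

# sweep tau grids over precomputed inner-fold step probabilities
route_probs <- function(prob_matrix, taus) {
  n <- nrow(prob_matrix)
  S <- ncol(prob_matrix)
  decided <- rep(FALSE, n)
  prob <- numeric(n)
  step_of <- integer(n)
  for (s in seq_len(S)) {
    p_s <- prob_matrix[, s]
    decide <- if (s < S) {
      if (taus[s] >= 1) rep(FALSE, n) else pmax(p_s, 1 - p_s) >= taus[s]
    } else rep(TRUE, n)
    take <- !decided & decide
    prob[take] <- p_s[take]
    step_of[take] <- s
    decided <- decided | take
  }
  list(probability = prob, step = step_of)
}

#' Tune propagation thresholds on inner cross-validation
#'
#' Trains every step model on each inner-training split, collects inner-test
#' probabilities, and evaluates the full threshold grid on the routed
#' predictions: the thresholds maximizing mean inner balanced accuracy win,
#' with ties broken by the smaller propagated fraction (fewer per-case
#' examinations) and then by the smaller threshold.
#'
#' @param step_specs List of model specs, one per step, in routing order
#'   (>= 2).
#' @param train Outer-training cohort rows.
#' @param inner_ids Inner fold id per training row.
#' @param tau_grid Candidate thresholds within `[0.5, 1]`.
#' @param control A [dep_control()].
#' @param seed Integer seed.
#' @return A [sequential_policy()] with a `tuning` attribute holding the
#'   per-candidate grid scores.
#' @export
optimize_policy <- function(step_specs, train, inner_ids, tau_grid,
                            control = dep_control(), seed = 1) {
  if (length(step_specs) < 2) abort_arg("a sequential policy needs at least two steps")
  if (length(tau_grid) == 0) abort_arg("`tau_grid` is empty")
  if (any(tau_grid < 0.5 | tau_grid > 1)) abort_arg("`tau_grid` must lie within [0.5, 1]")
  y <- check_labels(train$diagnosis)
  S <- length(step_specs)
  k <- max(inner_ids, na.rm = TRUE)

  fold_probs <- list()
  for (g in seq_len(k)) {
    tr <- which(inner_ids != g)
    te <- which(inner_ids == g)
    P <- matrix(NA_real_, length(te), S)
    for (s in seq_len(S)) {
      fit <- train_base_model(step_specs[[s]], train[tr, ],
                              seed = derive_seed(seed, paste0("opt", s, g)),
                              control = control)
      P[, s] <- predict_proba(fit, train[te, ])$probability
    }
    fold_probs[[g]] <- list(P = P, y = y[te])
  }

  grid <- do.call(expand.grid, rep(list(tau_grid), S - 1))
  names(grid) <- paste0("tau", seq_len(S - 1))
  scores <- purrr::pmap_dfr(grid, function(...) {
    taus <- c(...)
    per_fold <- purrr::map_dfr(fold_probs, function(fp) {
      r <- route_probs(fp$P, taus)
      tibble::tibble(bac = metric_triple(fp$y, as.integer(r$probability > 0.5))$bac,
                     propagated = mean(r$step > 1))
    })
    tibble::tibble(bac = mean(per_fold$bac), propagated = mean(per_fold$propagated))
  })
  tuning <- dplyr::bind_cols(grid, scores)
  ord <- order(-tuning$bac, tuning$propagated, rowSums(as.matrix(grid)))
  best <- tuning[ord[1], ]
  policy <- sequential_policy(as.numeric(best[paste0("tau", seq_len(S - 1))]),
                              step_names = purrr::map_chr(step_specs, "name"))
  attr(policy, "tuning") <- tuning
  policy
}

fit_sequential <- function(spec, train, inner_ids, control, seed) {
  base_fit <- train_base_model(spec$base, train, seed = derive_seed(seed, "seq_base"),
                               control = control)
  first_feats <- top_k_features(base_fit, spec$first_k)
  step1_spec <- structure(
    list(name = paste0(spec$base$name, "_first_", spec$first_k),
         pipeline = "P1", features = first_feats),
    class = "modality_model_spec"
  )
  step_specs <- c(list(step1_spec, spec$base), spec$extra_steps)
  policy <- optimize_policy(step_specs, train, inner_ids, spec$tau_grid,
                            control = control, seed = seed)
  models <- purrr::imap(step_specs, function(s, i) {
    if (i == 2 && length(spec$extra_steps) == 0) return(base_fit)
    if (identical(s$name, spec$base$name)) return(base_fit)
    train_base_model(s, train, seed = derive_seed(seed, paste0("seq_step", i)),
                     control = control)
  })
  list(kind = "sequential", models = models, policy = policy,
       first_features = first_feats)
}

format_count_pct <- function(correct, total) {
  ifelse(total == 0, "0/0 (-)",
         sprintf("%d/%d (%.1f%%)", correct, total, round(100 * correct / total, 1)))
}

#' Traffic-light classification report
#'
#' Cross-tabulates routed cases by traffic-light colour and true class,
#' counting correct classifications (prediction equals the true label) per
#' cell, with percentages rounded to one decimal. Zero-case cells report an
#' undefined percentage (`NA`), not 0.
#'
#' @param routing A [route_cases()] result (or any tibble with `label` and
#'   `colour`).
#' @param y_true 0/1 labels aligned to the routing rows.
#' @return A `traffic_light_report` tibble: `colour`, `class`, `correct`,
#'   `total`, `pct`.
#' @export
traffic_light_report <- function(routing, y_true) {
  y <- check_labels(y_true, "y_true")
  if (nrow(routing) != length(y)) abort_arg("routing and labels differ in length")
  grid <- tidyr::expand_grid(
    colour = factor(c("green", "yellow", "red"), levels = c("green", "yellow", "red")),
    class = c("depressed", "control")
  )
  counts <- tibble::tibble(
    colour = routing$colour,
    class = ifelse(y == 1, "depressed", "control"),
    correct = routing$label == y
  ) |>
    dplyr::group_by(.data$colour, .data$class) |>
    dplyr::summarise(correct = sum(.data$correct), total = dplyr::n(), .groups = "drop")
  out <- grid |>
    dplyr::left_join(counts, by = c("colour", "class")) |>
    dplyr::mutate(
      correct = dplyr::coalesce(.data$correct, 0L),
      total = dplyr::coalesce(.data$total, 0L),
      pct = dplyr::if_else(.data$total > 0,
                           round(100 * .data$correct / .data$total, 1), NA_real_)
    )
  class(out) <- c("traffic_light_report", class(out))
  out
}

#' Render a traffic-light report in the study's table layout
#'
#' One row per class with `x/y (z%)` cells: overall, high-certainty
#' (red light for true depression, green for true controls) and
#' low-certainty (yellow) columns.
#'
#' @param report A [traffic_light_report()].
#' @param model_name Row label.
#' @return A tibble with formatted cells.
#' @export
render_traffic_light <- function(report, model_name = "sequential") {
  get <- function(col, cls, what) {
    r <- report[report$colour == col & report$class == cls, ]
    sum(r[[what]])
  }
  # high-certainty cells pool the non-yellow cases of each true class
  hi <- function(cls) {
    tot <- get("red", cls, "total") + get("green", cls, "total")
    cor <- get("red", cls, "correct") + get("green", cls, "correct")
    format_count_pct(cor, tot)
  }
  total_cell <- function(cls) {
    tot <- sum(report$total[report$class == cls])
    cor <- sum(report$correct[report$class == cls])
    format_count_pct(cor, tot)
  }
  tibble::tibble(
    model = model_name,
    class = c("depressed", "control"),
    total = c(total_cell("depressed"), total_cell("control")),
    high_certainty = c(hi("depressed"), hi("control")),
    low_certainty = c(format_count_pct(get("yellow", "depressed", "correct"),
                                       get("yellow", "depressed", "total")),
                      format_count_pct(get("yellow", "control", "correct"),
                                       get("yellow", "control", "total")))
  )
}

#' @rdname tidy_depscreen
#' @method tidy traffic_light_report
#' @export
tidy.traffic_light_report <- function(x, ...) {
  tibble::as_tibble(x)
}
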