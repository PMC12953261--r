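#' Fit a rare-category aggregator
#'
#' Categories observed in less than `threshold` of the training rows are
#' merged into a single `"other"` level per feature; categories at or above
#' the threshold are kept. Categories unseen in training map to `"other"`
#' when the fitted map is applied.
#'
#' @param train A data frame; only factor/character columns are aggregated.
#' @param threshold Frequency threshold in `(0, 1)`, default 0.05.
#' @param columns Columns to fit; defaults to all categorical columns.
#' @return A named list of per-feature level maps, class `rare_aggregator`.
#' @export
fit_rare_aggregator <- function(train, threshold = 0.05, columns = NULL) {
  if (threshold <= 0 || threshold >= 1) abort_arg("`threshold` must lie in (0, 1)")
  is_cat <- vapply(train, function(x) is.factor(x) || is.character(x), logical(1))
  columns <- columns %||% names(train)[is_cat]
  bad <- columns[!is_cat[columns]]
  if (length(bad) > 0) {
    abort_arg(sprintf("non-categorical column(s): %s", paste(bad, collapse = ", ")))
  }
  maps <- purrr::map(purrr::set_names(columns), function(cn) {
    x <- as.character(train[[cn]])
    freq <- table(x[!is.na(x)]) / sum(!is.na(x))
    keep <- names(freq)[freq >= threshold]
    purrr::set_names(ifelse(names(freq) %in% keep, names(freq), "other"), names(freq))
  })
  structure(maps, class = "rare_aggregator", threshold = threshold)
}

#' Apply a fitted rare-category map
#'
#' @param map A `rare_aggregator`.
#' @param data Data frame to transform.
#' @return `data` with mapped categorical columns (factors with the retained
#'   levels plus `"other"` where used).
#' @export
apply_rare_aggregator <- function(map, data) {
  for (cn in names(map)) {
    if (!cn %in% names(data)) next
    x <- as.character(data[[cn]])
    m <- map[[cn]]
    mapped <- ifelse(is.na(x), NA_character_,
                     ifelse(x %in% names(m), unname(m[x]), "other"))
    data[[cn]] <- factor(mapped, levels = unique(c(sort(unique(unname(m))),
                                                   if (any(mapped == "other", na.rm = TRUE)) "other")))
  }
  data
}

#' k-nearest-neighbour imputation with a mixed-type, NA-aware distance
#'
#' Distances are Euclidean over mutually observed coordinates, rescaled by
#' the number of observed coordinates: continuous features are standardized
#' by training mean/sd and categorical features contribute a 0/1 mismatch
#' with weight one per feature. Each missing cell is replaced by the mean
#' (continuous) or mode (categorical; ties broken by the lexicographically
#' first level) of the `k` nearest training rows in which that feature is
#' observed. Observed cells are never touched, so applying a fitted
#' imputation to complete data is the identity.
#'
#' @param train Training data frame (reference set; fitted on this split
#'   only).
#' @param apply_to Data frame to complete; defaults to `train`.
#' @param k Number of neighbours (default 7).
#' @return `apply_to` with missing cells filled.
#' @export
fit_apply_knn_impute <- function(train, apply_to = train, k = 7) {
  if (k < 1) abort_arg("`k` must be >= 1")
  if (nrow(train) < k) abort_arg(sprintf("`k` = %d exceeds the %d training rows", k, nrow(train)))
  cols <- names(train)
  if (!identical(cols, names(apply_to))) abort_schema("train and apply_to must share columns")

  is_num <- vapply(train, is.numeric, logical(1))
  num_cols <- cols[is_num]
  cat_cols <- cols[!is_num]

  centers <- vapply(train[num_cols], function(x) mean(x, na.rm = TRUE), numeric(1))
  scales <- vapply(train[num_cols], function(x) {
    s <- stats::sd(x, na.rm = TRUE); if (is.na(s) || s == 0) 1 else s
  }, numeric(1))

  std <- function(df) {
    if (length(num_cols) == 0) return(matrix(numeric(0), nrow(df), 0))
    m <- vapply(df[num_cols], as.numeric, numeric(nrow(df)))
    m <- matrix(m, nrow(df), length(num_cols))
    sweep(sweep(m, 2, centers), 2, scales, `/`)
  }
  chr <- function(df) {
    if (length(cat_cols) == 0) return(matrix(character(0), nrow(df), 0))
    matrix(vapply(df[cat_cols], as.character, character(nrow(df))),
           nrow(df), length(cat_cols))
  }
  Tn <- std(train)
  An <- std(apply_to)
  Tc <- chr(train)
  Ac <- chr(apply_to)

  p <- length(cols)
  all_missing <- rowSums(!is.na(An)) + rowSums(!is.na(Ac)) == 0
  if (any(all_missing)) {
    abort_arg(sprintf("row(s) with every feature missing: %s",
                      paste(which(all_missing), collapse = ", ")))
  }

  need <- which(rowSums(is.na(An)) + rowSums(is.na(Ac)) > 0)
  out <- apply_to
  # work on character copies of categoricals so donor levels unseen in the
  # apply split cannot be dropped; factors are restored at the end
  was_factor <- vapply(apply_to, is.factor, logical(1))
  for (cn in names(out)[was_factor]) out[[cn]] <- as.character(out[[cn]])
  for (i in need) {
    d2 <- numeric(nrow(train))
    m <- numeric(nrow(train))
    for (j in seq_along(num_cols)) {
      xi <- An[i, j]
      if (is.na(xi)) next
      tj <- Tn[, j]
      obs <- !is.na(tj)
      d2[obs] <- d2[obs] + (xi - tj[obs])^2
      m <- m + obs
    }
    for (j in seq_along(cat_cols)) {
      xi <- Ac[i, j]
      if (is.na(xi)) next
      tj <- Tc[, j]
      obs <- !is.na(tj)
      d2[obs] <- d2[obs] + (xi != tj[obs])
      m <- m + obs
    }
    dist <- ifelse(m > 0, sqrt(p / pmax(m, 1) * d2), Inf)
    for (cn in cols) {
      val <- out[[cn]][i]
      if (!is.na(val)) next
      donor_obs <- if (cn %in% num_cols) !is.na(train[[cn]]) else !is.na(as.character(train[[cn]]))
      cand <- which(donor_obs & is.finite(dist))
      if (length(cand) == 0) abort_arg(sprintf("no observed training values for '%s'", cn))
      nb <- cand[order(dist[cand], cand)][seq_len(min(k, length(cand)))]
      if (cn %in% num_cols) {
        filled <- mean(as.numeric(train[[cn]][nb]))
        if (is.integer(out[[cn]])) filled <- as.integer(round(filled))
        out[[cn]][i] <- filled
      } else {
        vals <- as.character(train[[cn]][nb])
        tab <- table(vals)
        out[[cn]][i] <- sort(names(tab)[tab == max(tab)])[1]
      }
    }
  }
  for (cn in names(out)[was_factor]) {
    lv <- union(levels(apply_to[[cn]]),
                unique(as.character(train[[cn]][!is.na(train[[cn]])])))
    out[[cn]] <- factor(out[[cn]], levels = lv)
  }
  out
}

#' Yeo-Johnson transform at a fixed exponent
#'
#' The power transform defined for all real values: for `x >= 0`,
#' `((x+1)^lambda - 1) / lambda` (`log1p(x)` at `lambda = 0`); for `x < 0`,
#' `-((1-x)^(2-lambda) - 1) / (2-lambda)` (`-log1p(-x)` at `lambda = 2`).
#' Strictly monotone in `x` for every `lambda`; the identity at
#' `lambda = 1`.
#'
#' @param x Numeric vector.
#' @param lambda Exponent.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(x, lambda) yj_transform(x, lambda)

# Yeo-Johnson transform for one lambda (monotone for every lambda)
yj_transform <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

yj_loglik <- function(x, lambda) {
  z <- yj_transform(x, lambda)
  n <- length(x)
  s2 <- stats::var(z) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit and apply a Yeo-Johnson power transformation
#'
#' The per-feature exponent is chosen by maximum profile likelihood with a
#' bounded one-dimensional search on `[-5, 5]` (tolerance 1e-6); the
#' transformed training columns are then standardized to zero mean and unit
#' variance and the same affine map is applied to `apply_to`. Constant
#' features are passed through untransformed and flagged.
#'
#' @param train Complete (imputed) numeric matrix or data frame.
#' @param apply_to Matrix to transform with the fitted parameters; defaults
#'   to `train`.
#' @return A list: `transformed` (matrix for `apply_to`), `lambda` (named
#'   vector), `center`, `scale`, `constant` (logical flags). Class
#'   `yeo_johnson_fit`.
#' @export
fit_apply_yeo_johnson <- function(train, apply_to = train) {
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  if (anyNA(train) || anyNA(apply_to)) {
    abort_arg("Yeo-Johnson requires complete data; impute first")
  }
  p <- ncol(train)
  lambda <- numeric(p)
  constant <- logical(p)
  out <- matrix(NA_real_, nrow(apply_to), p, dimnames = dimnames(apply_to))
  centers <- numeric(p)
  scales <- numeric(p)
  for (j in seq_len(p)) {
    x <- train[, j]
    if (stats::sd(x) == 0) {
      constant[j] <- TRUE
      lambda[j] <- 1
      warning(sprintf("constant feature '%s': identity transform used",
                      colnames(train)[j] %||% j), call. = FALSE)
      centers[j] <- x[1]; scales[j] <- 1
      out[, j] <- apply_to[, j] - centers[j]
      next
    }
    opt <- stats::optimize(function(l) yj_loglik(x, l), interval = c(-5, 5),
                           maximum = TRUE, tol = 1e-6)
    lambda[j] <- opt$maximum
    zt <- yj_transform(x, lambda[j])
    centers[j] <- mean(zt)
    scales[j] <- stats::sd(zt)
    if (scales[j] == 0) scales[j] <- 1
    out[, j] <- (yj_transform(apply_to[, j], lambda[j]) - centers[j]) / scales[j]
  }
  names(lambda) <- colnames(train)
  structure(
    list(transformed = out, lambda = lambda, center = centers,
         scale = scales, constant = constant),
    class = "yeo_johnson_fit"
  )
}

# one-hot encoding with training levels; numeric passthrough.
# Returns a numeric matrix; unseen levels at apply time fall in no column.
fit_onehot <- function(train) {
  is_num <- vapply(train, is.numeric, logical(1))
  cat_levels <- purrr::map(
    purrr::set_names(names(train)[!is_num]),
    ~ sort(unique(as.character(train[[.x]][!is.na(train[[.x]])])))
  )
  structure(list(numeric = names(train)[is_num], cat_levels = cat_levels),
            class = "onehot_encoder")
}

apply_onehot <- function(enc, data) {
  parts <- list()
  for (cn in enc$numeric) parts[[cn]] <- as.numeric(data[[cn]])
  for (cn in names(enc$cat_levels)) {
    x <- as.character(data[[cn]])
    for (lv in enc$cat_levels[[cn]]) {
      parts[[paste0(cn, "=", lv)]] <- as.numeric(x == lv)
    }
  }
  do.call(cbind, parts)
}

#' Fit a fold-safe preprocessing plan
#'
#' Bundles rare-category aggregation (threshold `rare_threshold`) and
#' k-nearest-neighbour imputation (`knn_k` neighbours) fitted exclusively on
#' a training split, plus a one-hot encoding with training levels. Apply the
#' plan unchanged to held-out rows with [apply_preprocess_plan()].
#'
#' @param train Training data frame (features only, no label).
#' @param rare_threshold Rare-category threshold, default 0.05.
#' @param knn_k Imputation neighbours, default 7.
#' @return A `preprocess_plan`.
#' @export
fit_preprocess_plan <- function(train, rare_threshold = 0.05, knn_k = 7) {
  rare <- fit_rare_aggregator(train, threshold = rare_threshold)
  train_agg <- apply_rare_aggregator(rare, train)
  train_imp <- fit_apply_knn_impute(train_agg, train_agg, k = knn_k)
  enc <- fit_onehot(train_imp)
  structure(
    list(rare = rare, reference = train_imp, knn_k = knn_k, encoder = enc,
         columns = names(train)),
    class = "preprocess_plan"
  )
}

#' Apply a fitted preprocessing plan
#'
#' @param plan A `preprocess_plan`.
#' @param data Data frame with the plan's feature columns.
#' @return A numeric design matrix (aggregated, imputed, one-hot encoded).
#' @export
apply_preprocess_plan <- function(plan, data) {
  missing_cols <- setdiff(plan$columns, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("missing feature column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  data <- data[, plan$columns, drop = FALSE]
  data <- apply_rare_aggregator(plan$rare, data)
  if (anyNA(data)) {
    data <- fit_apply_knn_impute(plan$reference, data, k = plan$knn_k)
  }
  apply_onehot(plan$encoder, data)
}

#' Serialize a preprocessing plan to JSON for audit
#'
#' @param plan A `preprocess_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
plan_to_json <- function(plan, path) {
  jsonlite::write_json(
    list(
      rare_threshold = attr(plan$rare, "threshold"),
      rare_maps = purrr::map(unclass(plan$rare), as.list),
      knn_k = plan$knn_k,
      columns = plan$columns,
      encoded_columns = c(plan$encoder$numeric,
                          unlist(purrr::imap(plan$encoder$cat_levels,
                                             ~ paste0(.y, "=", .x))))
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
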