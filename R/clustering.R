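# covariance-structure names map to mclust model codes
cov_to_mclust <- c(full = "VVV", tied = "EEE", diag = "VVI", spherical = "VII")

#' Columns that enter the subtype clustering
#'
#' The clustering consumes only laboratory, heart-rate-variability /
#' bioimpedance and anthropometric features; questionnaire data never enter.
#'
#' @param cohort A cohort tibble with a data dictionary.
#' @param modalities Modality tags admitted to the clustering.
#' @return Character vector of column names.
#' @export
clustering_features <- function(cohort,
                                modalities = c("lab", "physiological", "anthropometric")) {
  dict <- cohort_dictionary(cohort)
  if (is.null(dict)) abort_schema("cohort carries no data dictionary")
  dict$column[dict$modality %in% modalities & dict$value_type %in% c("continuous", "ordinal")]
}

# one EM fit: best of n_init k-means starts plus one hierarchical-
# agglomeration start; optionally with a conjugate prior for degenerate
# covariances. Returns NULL when no start converges.
fit_gmm_once <- function(X, k, model_name, seed, n_init, prior = NULL) {
  withr::local_seed(seed)
  # the mclust wrapper functions resolve worker names in the calling frame,
  # so call the exported workers (meVVV, hcVVV, mvnXXX, ...) directly
  if (k == 1) {
    single <- switch(model_name, VII = "XII", VVI = "XXI", "XXX")
    mvn_fn <- getExportedValue("mclust", paste0("mvn", single))
    fit <- tryCatch(suppressWarnings(mvn_fn(data = X, prior = prior)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik %||% NA)) return(NULL)
    fit$z <- matrix(1, nrow(X), 1)
    fit$parameters$pro <- 1
    return(fit)
  }
  me_fn <- getExportedValue("mclust", paste0("me", model_name))
  em_from <- function(cl) {
    z <- mclust::unmap(cl, groups = seq_len(k))
    fit <- tryCatch(
      suppressWarnings(me_fn(data = X, z = z, prior = prior)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$loglik %||% NA)) return(NULL)
    fit
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    km <- tryCatch(stats::kmeans(X, centers = k, nstart = 1, iter.max = 30),
                   error = function(e) NULL)
    if (is.null(km)) next
    fit <- em_from(km$cluster)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  hc_fn <- getExportedValue("mclust", switch(model_name, EEE = "hcEEE",
                                             VII = "hcVII", "hcVVV"))
  hc_cl <- tryCatch(mclust::hclass(hc_fn(data = X), k),
                    error = function(e) NULL)
  if (!is.null(hc_cl)) {
    fit <- em_from(as.integer(hc_cl))
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  best
}

#' Scan Gaussian-mixture candidates and select a model
#'
#' Fits every (number of components, covariance structure) candidate by
#' expectation-maximization with `n_init` restarts and reports AIC, BIC and
#' the mean silhouette of the hard assignments. The chosen candidate
#' minimizes BIC, with ties resolved towards fewer parameters; AIC and
#' silhouette are reported alongside. Candidates whose EM fails to converge
#' are flagged, not dropped.
#'
#' @param X Complete (imputed), transformed feature matrix.
#' @param k_grid Component counts to scan (default 2:8).
#' @param cov_grid Covariance structures, a subset of
#'   `c("full", "tied", "diag", "spherical")`.
#' @param seed Integer seed.
#' @param n_init Random restarts per candidate.
#' @return A `gmm_selection`: `candidates` tibble (k, covariance, df,
#'   loglik, AIC, BIC, silhouette, converged) and `best` (k, covariance).
#' @export
select_gmm <- function(X, k_grid = 2:8,
                       cov_grid = c("full", "tied", "diag", "spherical"),
                       seed = 1, n_init = 10) {
  X <- as.matrix(X)
  if (anyNA(X)) abort_arg("X must be complete; impute before clustering")
  if (nrow(X) <= max(k_grid)) abort_arg("need more rows than the largest candidate k")
  bad <- setdiff(cov_grid, names(cov_to_mclust))
  if (length(bad) > 0) abort_arg(sprintf("unknown covariance structure(s): %s", paste(bad, collapse = ", ")))

  D <- stats::dist(X)
  rows <- list()
  for (cv in cov_grid) {
    for (k in k_grid) {
      fit <- fit_gmm_once(X, k, cov_to_mclust[[cv]],
                          seed = derive_seed(seed, paste0(cv, k)), n_init = n_init)
      if (is.null(fit)) {
        rows[[paste(cv, k)]] <- tibble::tibble(
          k = k, covariance = cv, df = NA_integer_, loglik = NA_real_,
          aic = NA_real_, bic = NA_real_, silhouette = NA_real_, converged = FALSE)
        next
      }
      df <- mclust::nMclustParams(cov_to_mclust[[cv]], d = ncol(X), G = k) + (k - 1)
      ll <- fit$loglik
      cl <- mclust::map(fit$z)
      sil <- if (k >= 2 && length(unique(cl)) >= 2) {
        mean(cluster::silhouette(cl, D)[, "sil_width"])
      } else NA_real_
      rows[[paste(cv, k)]] <- tibble::tibble(
        k = k, covariance = cv, df = as.integer(df), loglik = ll,
        aic = -2 * ll + 2 * df,
        bic = -2 * ll + df * log(nrow(X)),
        silhouette = sil, converged = TRUE)
    }
  }
  candidates <- dplyr::bind_rows(rows)
  ok <- candidates[candidates$converged & is.finite(candidates$bic), ]
  if (nrow(ok) == 0) abort_validation("no candidate converged")
  ok <- ok[order(ok$bic, ok$df), ]
  structure(
    list(candidates = candidates,
         best = list(k = ok$k[1], covariance = ok$covariance[1]),
         seed = seed, n_init = n_init),
    class = "gmm_selection"
  )
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("<gmm_selection> best: k = %d, covariance = %s\n",
              x$best$k, x$best$covariance))
  invisible(x)
}

#' Fit a Gaussian mixture and assign clusters
#'
#' Best-of-`n_init` expectation-maximization solution for a fixed number of
#' components and covariance structure. A singular covariance triggers a
#' diagonal ridge (1e-6) refit, flagged in the result.
#'
#' @param X Complete, transformed feature matrix.
#' @param k Number of components.
#' @param covariance One of `"full"`, `"tied"`, `"diag"`, `"spherical"`.
#' @param seed Integer seed.
#' @param n_init Random restarts.
#' @return A `cluster_solution`: `assignment`, `responsibilities`,
#'   `weights`, `means`, `loglik`, `df`, `bic`, `regularized`.
#' @export
fit_assign <- function(X, k = 4, covariance = "full", seed = 1, n_init = 10) {
  X <- as.matrix(X)
  if (anyNA(X)) abort_arg("X must be complete; impute before clustering")
  model_name <- cov_to_mclust[[covariance]]
  if (is.null(model_name)) abort_arg(sprintf("unknown covariance structure '%s'", covariance))
  fit <- fit_gmm_once(X, k, model_name, seed = derive_seed(seed, "fit"), n_init = n_init)
  regularized <- FALSE
  if (is.null(fit)) {
    # singular covariance: refit with a weak conjugate covariance prior
    fit <- fit_gmm_once(X, k, model_name, seed = derive_seed(seed, "fit2"),
                        n_init = n_init, prior = mclust::priorControl())
    regularized <- TRUE
    if (is.null(fit)) abort_validation("EM failed to converge even after regularization")
  }
  z <- fit$z
  df <- mclust::nMclustParams(model_name, d = ncol(X), G = k) + (k - 1)
  structure(
    list(k = k, covariance = covariance,
         assignment = as.integer(mclust::map(z)),
         responsibilities = z,
         weights = as.numeric(fit$parameters$pro),
         means = fit$parameters$mean,
         loglik = fit$loglik, df = as.integer(df),
         bic = -2 * fit$loglik + df * log(nrow(X)),
         regularized = regularized, seed = seed, n_init = n_init),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d (%s), sizes: %s\n",
              x$k, x$covariance, paste(table(x$assignment), collapse = "/")))
  invisible(x)
}

#' @rdname tidy_depscreen
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(
    case = seq_along(x$assignment),
    cluster = x$assignment,
    max_responsibility = apply(x$responsibilities, 1, max)
  )
}

#' @rdname tidy_depscreen
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, covariance = x$covariance, loglik = x$loglik,
                 df = x$df, bic = x$bic, regularized = x$regularized)
}

# Dunn's post-hoc test: pairwise z statistics on mean ranks after a
# Kruskal-Wallis omnibus, Bonferroni-adjusted
dunn_posthoc <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  mean_ranks <- tapply(r, g, mean)
  sizes <- table(g)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    se <- sqrt((n * (n + 1) / 12) * tie_corr * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    z <- (mean_ranks[pr[1]] - mean_ranks[pr[2]]) / se
    tibble::tibble(group1 = pr[1], group2 = pr[2], statistic = as.numeric(z),
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
  res$p_adj <- pmin(res$p_raw * nrow(res), 1)
  res
}

pairwise_chisq <- function(x, g) {
  g <- factor(g)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    sel <- g %in% pr
    tab <- table(droplevels(factor(x[sel])), droplevels(g[sel]))
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    tibble::tibble(group1 = pr[1], group2 = pr[2], statistic = NA_real_, p_raw = p)
  })
  res$p_adj <- pmin(res$p_raw * nrow(res), 1)
  res
}

#' Compare clusters variable by variable
#'
#' Profiles clusters on the imputed but untransformed data. Continuous
#' variables pass a Shapiro-Wilk normality gate (alpha 0.05 on the
#' model residuals): normal variables get a one-way ANOVA with Tukey HSD
#' post hocs, non-normal ones a Kruskal-Wallis test with eta-squared
#' effect size (`(H - k + 1) / (n - k)`) and Dunn post hocs with
#' Bonferroni correction. Categorical variables get an omnibus chi-square
#' with Bonferroni-adjusted pairwise chi-squares. Constant variables and
#' variables with a cluster of fewer than two observed cases are skipped
#' with a warning.
#'
#' @param solution A [fit_assign()] result.
#' @param raw Imputed, untransformed data aligned with the assignments.
#' @param posthoc_alpha Omnibus significance needed before post hocs run.
#' @return A `cluster_profile` tibble: per variable the per-cluster
#'   mean (sd) or percentage, test used, omnibus statistic and p-value,
#'   effect size, and a list-column of post-hoc pair results.
#' @export
profile_clusters <- function(solution, raw, posthoc_alpha = 0.05) {
  cl <- factor(solution$assignment)
  if (nrow(raw) != length(cl)) abort_arg("raw data and assignments differ in length")
  k <- nlevels(cl)
  rows <- list()
  for (v in names(raw)) {
    x <- raw[[v]]
    obs <- !is.na(x)
    per_cl <- table(cl[obs])
    if (any(per_cl < 2)) {
      warning(sprintf("variable '%s' skipped: a cluster has fewer than 2 observed cases", v),
              call. = FALSE)
      next
    }
    if (is.numeric(x)) {
      if (stats::sd(x[obs]) == 0) {
        warning(sprintf("constant variable '%s' skipped", v), call. = FALSE)
        next
      }
      res <- tryCatch(stats::residuals(stats::lm(x ~ cl)), error = function(e) NULL)
      normal <- !is.null(res) && length(unique(round(res, 12))) > 2 &&
        isTRUE(tryCatch(stats::shapiro.test(res)$p.value >= 0.05,
                        error = function(e) FALSE))
      summary_cells <- tapply(x[obs], cl[obs], function(u) sprintf("%.2f (%.2f)", mean(u), stats::sd(u)))
      if (normal) {
        fit <- stats::aov(x ~ cl)
        an <- summary(fit)[[1]]
        pval <- an$`Pr(>F)`[1]
        stat <- an$`F value`[1]
        eta2 <- an$`Sum Sq`[1] / sum(an$`Sum Sq`)
        ph <- if (!is.na(pval) && pval < posthoc_alpha) {
          t <- as.data.frame(stats::TukeyHSD(fit)$cl)
          tibble::tibble(group1 = sub("-.*", "", rownames(t)),
                         group2 = sub(".*-", "", rownames(t)),
                         statistic = t$diff, p_raw = t$`p adj`, p_adj = t$`p adj`)
        }
        test <- "anova"
      } else {
        kw <- stats::kruskal.test(x[obs], cl[obs])
        pval <- kw$p.value
        stat <- unname(kw$statistic)
        eta2 <- (stat - k + 1) / (sum(obs) - k)
        ph <- if (!is.na(pval) && pval < posthoc_alpha) dunn_posthoc(x[obs], cl[obs])
        test <- "kruskal"
      }
    } else {
      tab <- table(droplevels(factor(x[obs])), cl[obs])
      if (nrow(tab) < 2) {
        warning(sprintf("constant variable '%s' skipped", v), call. = FALSE)
        next
      }
      summary_cells <- vapply(levels(cl), function(l) {
        xx <- factor(x[obs])[cl[obs] == l]
        top <- names(sort(table(xx), decreasing = TRUE))[1]
        sprintf("%s: %.1f%%", top, 100 * mean(xx == top))
      }, character(1))
      ct <- tryCatch(suppressWarnings(stats::chisq.test(tab)), error = function(e) NULL)
      pval <- ct$p.value %||% NA_real_
      stat <- unname(ct$statistic %||% NA_real_)
      eta2 <- NA_real_
      ph <- if (!is.na(pval) && pval < posthoc_alpha) pairwise_chisq(x[obs], cl[obs])
      test <- "chisq"
    }
    cells <- purrr::set_names(as.list(summary_cells), paste0("cluster_", levels(cl)))
    rows[[v]] <- dplyr::bind_cols(
      tibble::tibble(variable = v, test = test, statistic = stat,
                     p_value = pval, eta_squared = eta2),
      tibble::as_tibble(cells),
      tibble::tibble(posthoc = list(ph))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_profile", class(out))
  attr(out, "k") <- k
  out
}

#' Name the four depression subtypes from their profiles
#'
#' Rule-based post-hoc labelling on cluster means of the untransformed
#' data: the cluster with the highest C-reactive protein, lowest
#' heart-rate-variability SDNN and highest Baevskii stress index is
#' `ImmunoMetabolic`; among the rest, the highest body-mass index with
#' non-elevated CRP is `OverweightNonInflammatory`; the oldest remaining
#' cluster is `LateDepression`; the remainder is `Adaptive`. The names are
#' descriptive metadata only. Ties on a deciding feature leave the labels
#' unresolved with a diagnostic.
#'
#' @param solution A [fit_assign()] result with `k = 4`.
#' @param raw Imputed, untransformed data with `crp`, `hrv_sdnn`,
#'   `hrv_baevskii`, `bmi`, `age` columns.
#' @return A named character vector mapping cluster id to subtype label, or
#'   (for `k != 4` or unresolved rules) `NULL` with a message/warning.
#' @export
label_clusters <- function(solution, raw) {
  if (solution$k != 4) {
    message("labelling skipped: subtype naming is defined for k = 4 solutions")
    return(NULL)
  }
  cl <- factor(solution$assignment)
  need <- c("crp", "hrv_sdnn", "hrv_baevskii", "bmi", "age")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("labelling needs column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  m <- function(v) tapply(raw[[v]], cl, mean, na.rm = TRUE)
  crp <- m("crp"); sdnn <- m("hrv_sdnn"); baev <- m("hrv_baevskii")
  bmi <- m("bmi"); age <- m("age")

  tie <- function(v) sum(v == max(v, na.rm = TRUE)) > 1 || anyNA(v)
  if (tie(crp) || tie(-sdnn) || tie(baev)) {
    warning("unresolved labels: ties on the immuno-metabolic deciding features", call. = FALSE)
    return(NULL)
  }
  votes <- table(c(names(which.max(crp)), names(which.max(-sdnn)), names(which.max(baev))))
  if (max(votes) < 2) {
    warning("unresolved labels: the immuno-metabolic criteria point to three different clusters",
            call. = FALSE)
    return(NULL)
  }
  imm <- names(which.max(votes))
  rest <- setdiff(levels(cl), imm)
  if (tie(bmi[rest])) {
    warning("unresolved labels: tie on body-mass index", call. = FALSE)
    return(NULL)
  }
  over <- rest[which.max(bmi[rest])]
  rest <- setdiff(rest, over)
  if (tie(age[rest])) {
    warning("unresolved labels: tie on age", call. = FALSE)
    return(NULL)
  }
  late <- rest[which.max(age[rest])]
  adaptive <- setdiff(rest, late)
  labels <- purrr::set_names(character(4), levels(cl))
  labels[imm] <- "ImmunoMetabolic"
  labels[over] <- "OverweightNonInflammatory"
  labels[late] <- "LateDepression"
  labels[adaptive] <- "Adaptive"
  labels
}
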