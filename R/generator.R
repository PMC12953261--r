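#' Specify a synthetic cohort draw
#'
#' The generator emulates a primary-care screening cohort: a fixed number of
#' depressed and non-depressed participants with questionnaire items and
#' totals, blood biomarkers, heart-rate-variability indices, anthropometrics
#' and biographic variables. Depressed participants carry one of four latent
#' subtypes whose biomarker profiles override the group-level parameters.
#'
#' @param n_total Total number of participants (>= 1).
#' @param n_depressed Number of participants labelled depressed; the split is
#'   deterministic, not binomial. Defaults to the study's 90/581.
#' @param seed Integer seed; equal specs give byte-identical cohorts.
#' @param rho Exchangeable within-block correlation of continuous features
#'   (default 0.3); blocks are the modality groups of the data dictionary.
#' @param missing_rate Probability in `[0, 1)` that a feature cell is masked
#'   missing-completely-at-random (0 = complete data).
#' @param subtype Optional subtype name; forces every depressed participant
#'   into that subtype (used for subtype-calibration checks).
#' @param subtype_weights Optional named mixing weights over the four
#'   subtypes; defaults to weights proportional to the printed cluster sizes.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_total = 581, n_depressed = 90, seed = 1,
                           rho = 0.3, missing_rate = 0,
                           subtype = NULL, subtype_weights = NULL) {
  if (!is.numeric(n_total) || n_total < 1) abort_arg("`n_total` must be >= 1")
  if (n_depressed < 0 || n_depressed > n_total) {
    abort_arg("`n_depressed` must lie in [0, n_total]")
  }
  if (rho < 0 || rho >= 1) abort_arg("`rho` must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) abort_arg("`missing_rate` must lie in [0, 1)")
  structure(
    list(n_total = as.integer(n_total), n_depressed = as.integer(n_depressed),
         seed = as.integer(seed), rho = rho, missing_rate = missing_rate,
         subtype = subtype, subtype_weights = subtype_weights),
    class = "generator_spec"
  )
}

#' Allocate a questionnaire total over its items
#'
#' Partitions an integer total into item scores by drawing, uniformly without
#' replacement, `total - items * min` unit increments from the
#' `items * (max - min)` available increment slots. Every allocation respects
#' the item bounds and sums exactly to the (clipped, rounded) total; the
#' split is random, not a deterministic rounding.
#'
#' @param total Total score (clipped into the feasible range and rounded).
#' @param scale A list with `items`, `min`, `max` (as in
#'   `load_profiles()$scales`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An integer vector of length `scale$items`.
#' @export
#' @examples
#' allocate_item_scores(14, list(items = 9, min = 0, max = 3), seed = 1)
allocate_item_scores <- function(total, scale, seed = NULL) {
  if (scale$min > scale$max) abort_arg("impossible scale: min item score exceeds max")
  if (!is.null(seed)) withr::local_seed(seed)
  k <- scale$items
  span <- scale$max - scale$min
  total <- round(min(max(total, k * scale$min), k * scale$max))
  extra <- total - k * scale$min
  items <- rep.int(scale$min, k)
  if (extra > 0 && span > 0) {
    slots <- sample.int(k * span, extra)
    items <- items + tabulate(((slots - 1L) %% k) + 1L, nbins = k)
  }
  as.integer(items)
}

#' Generate a synthetic cohort
#'
#' Draws a participant table from calibration profiles: continuous features
#' come from per-group (per-subtype, for the depressed biomarker panel)
#' multivariate normals with exchangeable within-block correlation, clipped
#' to the plausibility bounds of the data dictionary; categorical features
#' are drawn independently from the profile probabilities; questionnaire
#' totals are drawn first and their items allocated by a seeded random
#' partition.
#'
#' @param spec A [generator_spec()].
#' @param profiles A [load_profiles()] object.
#' @return A `cohort_tbl` tibble with columns `participant_id`, `diagnosis`
#'   (0/1), `subtype` (NA for non-depressed rows), the feature columns and
#'   the questionnaire item columns. The data dictionary is attached as the
#'   `"dictionary"` attribute.
#' @export
#' @examples
#' cohort <- sample_cohort(generator_spec(n_total = 100, n_depressed = 20, seed = 1))
#' dplyr::count(cohort, diagnosis)
sample_cohort <- function(spec = generator_spec(), profiles = load_profiles()) {
  stopifnot(inherits(spec, "generator_spec"), inherits(profiles, "cohort_profiles"))
  withr::local_seed(spec$seed)

  n <- spec$n_total
  n_dep <- spec$n_depressed
  diagnosis <- c(rep(1L, n_dep), rep(0L, n - n_dep))

  subtype <- rep(NA_character_, n)
  if (n_dep > 0) {
    subtype[seq_len(n_dep)] <- draw_subtypes(n_dep, spec, profiles)
  }

  feats <- profiles$features
  out <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    diagnosis = diagnosis,
    subtype = subtype
  )

  # continuous/ordinal features, block by block so the exchangeable
  # correlation acts within each modality block
  cont <- feats[feats$type %in% c("continuous", "ordinal"), ]
  for (blk in unique(cont$block)) {
    bf <- cont[cont$block == blk, ]
    vals <- draw_block(bf, diagnosis, subtype, spec$rho)
    for (j in seq_len(nrow(bf))) {
      v <- pmin(pmax(vals[, j], bf$lower[j]), bf$upper[j])
      if (bf$type[j] == "ordinal") v <- as.integer(round(v))
      out[[bf$name[j]]] <- v
    }
  }

  # binary / categorical features: independent draws from group probabilities
  disc <- feats[feats$type %in% c("binary", "categorical"), ]
  for (j in seq_len(nrow(disc))) {
    f <- disc[j, ]
    if (f$type == "binary") {
      p <- ifelse(diagnosis == 1, f$depressed[[1]]$p, f$non_depressed[[1]]$p)
      out[[f$name]] <- as.integer(stats::rbinom(n, 1, p))
    } else {
      lv <- f$levels[[1]]
      v <- character(n)
      for (grp in c(0L, 1L)) {
        idx <- which(diagnosis == grp)
        pr <- if (grp == 1L) f$depressed[[1]]$probs else f$non_depressed[[1]]$probs
        if (length(idx) > 0) v[idx] <- sample(lv, length(idx), replace = TRUE, prob = pr)
      }
      out[[f$name]] <- factor(v, levels = lv)
    }
  }

  # questionnaire items from the totals drawn above
  for (sc_name in names(profiles$scales)) {
    sc <- profiles$scales[[sc_name]]
    totals <- out[[sc$total]]
    items <- t(vapply(totals, allocate_item_scores, integer(sc$items), scale = sc))
    colnames(items) <- sprintf("%s_item_%d", sc_name, seq_len(sc$items))
    for (cn in colnames(items)) out[[cn]] <- items[, cn]
  }

  attr(out, "dictionary") <- cohort_dictionary(profiles)
  class(out) <- c("cohort_tbl", class(out))

  if (spec$missing_rate > 0) {
    out <- inject_missingness(out, spec$missing_rate,
                              seed = derive_seed(spec$seed, "missingness"))
  }
  out
}

# deterministic largest-remainder subtype allocation, then a seeded shuffle
draw_subtypes <- function(n_dep, spec, profiles) {
  if (!is.null(spec$subtype)) {
    if (!spec$subtype %in% names(profiles$subtype_sizes)) {
      abort_arg(sprintf("unknown subtype '%s'", spec$subtype))
    }
    return(rep(spec$subtype, n_dep))
  }
  w <- spec$subtype_weights %||% profiles$subtype_weights
  if (is.null(names(w)) || !setequal(names(w), names(profiles$subtype_sizes))) {
    abort_arg("`subtype_weights` must be named over the four subtypes")
  }
  w <- w[names(profiles$subtype_sizes)] / sum(w)
  quota <- n_dep * w
  counts <- floor(quota)
  rem <- n_dep - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(counts), counts))
}

# draw one modality block: exchangeable-correlation Gaussian per stratum,
# with subtype overrides substituting the depressed-group mean/sd where given
draw_block <- function(bf, diagnosis, subtype, rho) {
  n <- length(diagnosis)
  p <- nrow(bf)
  # standard-normal block with exchangeable correlation rho
  common <- stats::rnorm(n)
  z <- sqrt(rho) * matrix(common, n, p) + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)

  strata <- ifelse(diagnosis == 1, paste0("dep:", subtype), "nondep")
  vals <- matrix(NA_real_, n, p)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    mu <- numeric(p); sd <- numeric(p)
    for (j in seq_len(p)) {
      if (s == "nondep") {
        par <- bf$non_depressed[[j]]
      } else {
        st <- sub("^dep:", "", s)
        ov <- bf$subtypes[[j]]
        par <- if (!is.null(ov) && !is.null(ov[[st]])) ov[[st]] else bf$depressed[[j]]
      }
      mu[j] <- par$mean; sd[j] <- par$sd
    }
    vals[idx, ] <- sweep(sweep(z[idx, , drop = FALSE], 2, sd, `*`), 2, mu, `+`)
  }
  vals
}

#' Mask cells missing completely at random
#'
#' @param table A cohort tibble.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with roughly `rate` of the maskable cells set to `NA`.
#'   `participant_id`, `diagnosis` and `subtype` are never masked.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  if (rate < 0 || rate >= 1) abort_arg("`rate` must lie in [0, 1)")
  if (rate == 0) return(table)
  withr::local_seed(seed)
  protected <- c("participant_id", "diagnosis", "subtype")
  for (cn in setdiff(names(table), protected)) {
    mask <- stats::runif(nrow(table)) < rate
    table[[cn]][mask] <- NA
  }
  table
}
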