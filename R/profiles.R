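#' Load cohort calibration profiles
#'
#' Reads the YAML transcription of the study's descriptive tables: per-group
#' (depressed / non-depressed) marginal means and standard deviations for
#' continuous features, category probabilities for categorical features,
#' questionnaire scale definitions, and the four latent depression-subtype
#' overrides for the biomarker panel. The returned object drives
#' [sample_cohort()].
#'
#' Validation enforces: non-negative standard deviations, category
#' probabilities summing to one (printed rates that sum to within 0.05 of one
#' are renormalized, anything farther off is rejected), increasing bounds,
#' known modality and value-type tags, and subtype mixing sizes that sum to
#' the depressed group size.
#'
#' @param path Path to a profile fixture; defaults to the calibration fixture
#'   shipped with the package.
#' @return An object of class `cohort_profiles`: a list with elements
#'   `groups` (named group sizes), `subtype_sizes` (named subtype sizes),
#'   `scales` (questionnaire item scales) and `features` (a tibble with one
#'   row per feature and list-columns holding the per-group and per-subtype
#'   parameters).
#' @export
#' @examples
#' prof <- load_profiles()
#' profile_param(prof, "phq9_total", "depressed")
load_profiles <- function(path = default_profile_path()) {
  if (!file.exists(path)) abort_arg(sprintf("profile fixture '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  for (fld in c("groups", "subtype_sizes", "scales", "features")) {
    if (is.null(raw[[fld]])) abort_schema(sprintf("profile fixture is missing section '%s'", fld))
  }

  modalities <- c("self_report_item", "self_report_total", "lab",
                  "physiological", "anthropometric", "biographic")
  value_types <- c("continuous", "ordinal", "binary", "categorical")
  subtype_names <- names(raw$subtype_sizes)

  feats <- purrr::imap(raw$features, function(f, nm) {
    where <- sprintf("feature '%s'", nm)
    if (!isTRUE(f$modality %in% modalities)) {
      abort_schema(sprintf("%s: unknown modality '%s'", where, f$modality %||% "<missing>"))
    }
    if (!isTRUE(f$type %in% value_types)) {
      abort_schema(sprintf("%s: unknown value type '%s'", where, f$type %||% "<missing>"))
    }
    if (f$type %in% c("continuous", "ordinal")) {
      if (is.null(f$units)) abort_schema(sprintf("%s: continuous feature without units", where))
      bounds <- unlist(f$bounds)
      if (length(bounds) != 2 || !is.numeric(bounds) || bounds[1] >= bounds[2]) {
        abort_schema(sprintf("%s: bounds must be two increasing numbers", where))
      }
      for (grp in c("non_depressed", "depressed")) {
        p <- f[[grp]]
        if (is.null(p$mean) || is.null(p$sd)) {
          abort_schema(sprintf("%s: missing mean/sd for group '%s'", where, grp))
        }
        if (p$sd < 0) abort_validation(sprintf("%s: negative sd for group '%s'", where, grp))
      }
      subtypes <- f$subtypes
      if (!is.null(subtypes)) {
        if (!setequal(names(subtypes), subtype_names)) {
          abort_schema(sprintf("%s: subtype overrides must cover exactly: %s",
                               where, paste(subtype_names, collapse = ", ")))
        }
        bad <- purrr::keep(subtypes, ~ is.null(.x$mean) || is.null(.x$sd) || .x$sd < 0)
        if (length(bad) > 0) {
          abort_validation(sprintf("%s: invalid subtype override for %s",
                                   where, paste(names(bad), collapse = ", ")))
        }
      }
      tibble::tibble(
        name = nm, modality = f$modality, type = f$type,
        units = f$units, block = f$block %||% f$modality,
        lower = bounds[1], upper = bounds[2],
        scale = f$scale %||% NA_character_,
        levels = list(NULL),
        non_depressed = list(list(mean = f$non_depressed$mean, sd = f$non_depressed$sd)),
        depressed = list(list(mean = f$depressed$mean, sd = f$depressed$sd)),
        subtypes = list(subtypes)
      )
    } else if (f$type == "binary") {
      for (grp in c("non_depressed", "depressed")) {
        p <- f[[grp]]$p
        if (is.null(p) || p < 0 || p > 1) {
          abort_validation(sprintf("%s: binary probability for '%s' outside [0, 1]", where, grp))
        }
      }
      tibble::tibble(
        name = nm, modality = f$modality, type = "binary",
        units = f$units %||% "indicator", block = f$block %||% f$modality,
        lower = 0, upper = 1, scale = NA_character_, levels = list(NULL),
        non_depressed = list(list(p = f$non_depressed$p)),
        depressed = list(list(p = f$depressed$p)),
        subtypes = list(NULL)
      )
    } else {
      lv <- unlist(f$levels)
      if (length(lv) < 2) abort_schema(sprintf("%s: categorical feature needs >= 2 levels", where))
      norm <- function(pr, grp) {
        pr <- unlist(pr)
        if (length(pr) != length(lv)) {
          abort_schema(sprintf("%s: %d probabilities for %d levels in group '%s'",
                               where, length(pr), length(lv), grp))
        }
        if (any(pr < 0)) abort_validation(sprintf("%s: negative probability in group '%s'", where, grp))
        s <- sum(pr)
        if (abs(s - 1) > 0.05) {
          abort_validation(sprintf("%s: probabilities in group '%s' sum to %.3f, not 1", where, grp, s))
        }
        pr / s
      }
      tibble::tibble(
        name = nm, modality = f$modality, type = "categorical",
        units = f$units %||% "category", block = f$block %||% f$modality,
        lower = NA_real_, upper = NA_real_, scale = NA_character_, levels = list(lv),
        non_depressed = list(list(probs = norm(f$non_depressed$probs, "non_depressed"))),
        depressed = list(list(probs = norm(f$depressed$probs, "depressed"))),
        subtypes = list(NULL)
      )
    }
  })
  features <- dplyr::bind_rows(feats)

  scales <- purrr::imap(raw$scales, function(s, nm) {
    if (s$min > s$max) abort_schema(sprintf("scale '%s': min item score exceeds max", nm))
    if (s$items < 1) abort_schema(sprintf("scale '%s': needs at least one item", nm))
    list(items = as.integer(s$items), min = as.integer(s$min),
         max = as.integer(s$max), total = s$total)
  })

  sizes <- unlist(raw$subtype_sizes)
  if (sum(sizes) != raw$groups$depressed) {
    abort_validation(sprintf("subtype sizes sum to %d but the depressed group has %d members",
                             sum(sizes), raw$groups$depressed))
  }

  structure(
    list(
      groups = unlist(raw$groups),
      subtype_sizes = sizes,
      subtype_weights = sizes / sum(sizes),
      scales = scales,
      features = features
    ),
    class = "cohort_profiles"
  )
}

default_profile_path <- function() {
  system.file("extdata", "cohort_profiles.yaml", package = "depscreen", mustWork = TRUE)
}

#' @export
print.cohort_profiles <- function(x, ...) {
  cat(sprintf("<cohort_profiles> %d features, groups: %s\n",
              nrow(x$features),
              paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", ")))
  cat(sprintf("  subtypes: %s\n",
              paste(sprintf("%s=%d", names(x$subtype_sizes), x$subtype_sizes), collapse = ", ")))
  invisible(x)
}

#' Look up a profile parameter
#'
#' @param profiles A `cohort_profiles` object.
#' @param feature Feature name.
#' @param group `"depressed"`, `"non_depressed"`, or a subtype name for the
#'   depressed biomarker overrides.
#' @return A named list of parameters (`mean`/`sd`, `p`, or `probs`).
#' @export
profile_param <- function(profiles, feature, group) {
  row <- profiles$features[profiles$features$name == feature, ]
  if (nrow(row) == 0) abort_arg(sprintf("unknown feature '%s'", feature))
  if (group %in% c("depressed", "non_depressed")) {
    return(row[[group]][[1]])
  }
  st <- row$subtypes[[1]]
  if (is.null(st) || is.null(st[[group]])) {
    abort_arg(sprintf("feature '%s' has no override for subtype '%s'", feature, group))
  }
  st[[group]]
}

#' Data dictionary for the synthetic cohort
#'
#' Maps every generated column to its modality tag, value type, units and
#' plausibility bounds. Questionnaire item columns are included alongside the
#' totals they sum to.
#'
#' @param profiles A `cohort_profiles` object (or a generated cohort, whose
#'   dictionary was attached at generation time).
#' @return A tibble with columns `column`, `modality`, `value_type`, `units`,
#'   `lower`, `upper`, `block`.
#' @export
cohort_dictionary <- function(profiles = load_profiles()) {
  if (inherits(profiles, "cohort_tbl") || !is.null(attr(profiles, "dictionary"))) {
    return(attr(profiles, "dictionary"))
  }
  stopifnot(inherits(profiles, "cohort_profiles"))
  feats <- profiles$features
  base <- tibble::tibble(
    column = feats$name, modality = feats$modality, value_type = feats$type,
    units = feats$units, lower = feats$lower, upper = feats$upper,
    block = feats$block
  )
  items <- purrr::imap(profiles$scales, function(s, nm) {
    tibble::tibble(
      column = sprintf("%s_item_%d", nm, seq_len(s$items)),
      modality = "self_report_item", value_type = "ordinal", units = "score",
      lower = s$min, upper = s$max, block = "self_report"
    )
  })
  dplyr::bind_rows(base, !!!items)
}
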