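#' Configure an end-to-end study run
#'
#' @param generator A [generator_spec()] describing the cohort.
#' @param models Registry names of base models to evaluate.
#' @param stack Registry names of stack members (`NULL` disables the
#'   stacked-model stage; needs >= 2 names).
#' @param sequential_base Registry name behind the sequential model (`NULL`
#'   disables the stage).
#' @param tau_grid Propagation-threshold grid for the sequential model.
#' @param phq9_cutoff Screening cutoff for the questionnaire baseline.
#' @param clustering `TRUE` to run the depressed-subgroup subtyping stage.
#' @param k_grid,cov_grid Gaussian-mixture candidate grid.
#' @param seed Run seed; per-stage seeds are derived with [derive_seed()].
#' @param control A [dep_control()].
#' @param out_dir Output directory for the report bundle.
#' @return A `study_config` list.
#' @export
study_config <- function(generator = generator_spec(),
                         models = model_registry()$name,
                         stack = NULL,
                         sequential_base = "clinical_15",
                         tau_grid = seq(0.5, 1, by = 0.05),
                         phq9_cutoff = 8,
                         clustering = TRUE,
                         k_grid = 2:8,
                         cov_grid = c("full", "tied", "diag", "spherical"),
                         seed = 42,
                         control = dep_control(),
                         out_dir = tempfile("depscreen_study_")) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the full study pipeline
#'
#' Generates the cohort, evaluates the configured base models under nested
#' cross-validation, optionally trains the stacked and sequential models,
#' computes the questionnaire cutoff baseline, and clusters the depressed
#' subgroup. Each stage writes its report to the bundle directory as CSV;
#' a run log records seeds and stage outcomes. A failing stage marks the
#' bundle incomplete but preserves the reports already written.
#'
#' @param config A [study_config()].
#' @return Invisibly, a `study_bundle` list with the in-memory results and
#'   the paths written.
#' @export
run_study <- function(config = study_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat(sprintf("depscreen %s study run, seed %d\n",
              as.character(utils::packageVersion("depscreen")), config$seed),
      file = log_path)
  bundle <- list(paths = character(0), complete = TRUE)
  registry <- model_registry()
  add_path <- function(p) bundle$paths <<- c(bundle$paths, p)

  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) {
      log_line("stage %s FAILED: %s", stage, conditionMessage(e))
      bundle$complete <<- FALSE
      NULL
    })
    if (!is.null(res)) log_line("stage %s ok", stage)
    res
  }

  cohort <- run_stage("generate", function() {
    sample_cohort(config$generator)
  })
  if (is.null(cohort)) {
    log_line("bundle incomplete")
    return(invisible(structure(bundle, class = "study_bundle")))
  }
  write_cohort(cohort, config$out_dir)
  bundle$cohort <- cohort
  plan <- make_fold_plan(cohort$diagnosis, seed = derive_seed(config$seed, "folds"))

  base_reports <- run_stage("base_models", function() {
    reports <- purrr::map(config$models, function(nm) {
      evaluate_nested(modality_model_spec(nm, registry), cohort, plan,
                      control = config$control,
                      seed = derive_seed(config$seed, paste0("base_", nm)))
    })
    tbl <- purrr::map2_dfr(reports, config$models, function(r, nm) {
      row <- registry[registry$name == nm, ]
      tibble::tibble(model = nm, modalities = row$modalities,
                     features = row$features_printed, pipeline = row$pipeline,
                     bac = pct1(r$mean$bac), sens = pct1(r$mean$sensitivity),
                     spec = pct1(r$mean$specificity))
    })
    path <- file.path(config$out_dir, "base_models.csv")
    readr::write_csv(tbl, path)
    add_path(path)
    list(reports = purrr::set_names(reports, config$models), table = tbl)
  })
  bundle$base_models <- base_reports

  if (!is.null(config$stack)) {
    bundle$stack <- run_stage("stacked", function() {
      rep <- evaluate_nested(stack_spec(config$stack, registry = registry),
                             cohort, plan, control = config$control,
                             seed = derive_seed(config$seed, "stack"))
      tbl <- dplyr::mutate(glance(rep), dplyr::across(c("bac", "sensitivity", "specificity"), pct1))
      path <- file.path(config$out_dir, "stacked_models.csv")
      readr::write_csv(tbl, path)
      add_path(path)
      rep
    })
  }

  if (!is.null(config$sequential_base)) {
    bundle$sequential <- run_stage("sequential", function() {
      rep <- evaluate_nested(
        sequential_spec(config$sequential_base, tau_grid = config$tau_grid,
                        registry = registry),
        cohort, plan, control = config$control,
        seed = derive_seed(config$seed, "sequential"))
      y_routed <- cohort$diagnosis[match(rep$routing$participant_id,
                                         cohort$participant_id)]
      tl <- traffic_light_report(rep$routing, y_routed)
      rendered <- render_traffic_light(tl, model_name = config$sequential_base)
      path <- file.path(config$out_dir, "sequential_traffic_light.csv")
      readr::write_csv(rendered, path)
      add_path(path)
      list(report = rep, traffic_light = tl, rendered = rendered)
    })
  }

  bundle$phq9_baseline <- run_stage("phq9_baseline", function() {
    m <- phq9_cutoff_baseline(cohort, cutoff = config$phq9_cutoff)
    path <- file.path(config$out_dir, "phq9_baseline.csv")
    readr::write_csv(dplyr::mutate(m, cutoff = config$phq9_cutoff), path)
    add_path(path)
    m
  })

  if (isTRUE(config$clustering)) {
    bundle$clustering <- run_stage("clustering", function() {
      dep <- cohort[cohort$diagnosis == 1, ]
      feats <- clustering_features(cohort)
      raw <- fit_apply_knn_impute(dep[, feats], k = config$control$knn_k)
      yj <- fit_apply_yeo_johnson(raw)
      sel <- select_gmm(yj$transformed, k_grid = config$k_grid,
                        cov_grid = config$cov_grid,
                        seed = derive_seed(config$seed, "gmm"))
      sol <- fit_assign(yj$transformed, k = sel$best$k,
                        covariance = sel$best$covariance,
                        seed = derive_seed(config$seed, "gmm_fit"))
      prof <- suppressWarnings(profile_clusters(sol, raw))
      labels <- if (sol$k == 4) suppressWarnings(label_clusters(sol, raw))
      path <- file.path(config$out_dir, "cluster_profiles.csv")
      readr::write_csv(dplyr::select(prof, -"posthoc"), path)
      add_path(path)
      list(selection = sel, solution = sol, profile = prof, labels = labels)
    })
  }

  log_line(if (bundle$complete) "bundle complete" else "bundle incomplete")
  bundle$paths <- c(bundle$paths, log_path)
  invisible(structure(bundle, class = "study_bundle"))
}
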