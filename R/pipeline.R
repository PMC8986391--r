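#' Pipeline run configuration
#'
#' One object drives the whole analysis: cohort source, median-model
#' source, risk-model options, evaluation options, output directory and
#' the master seed.  The configuration round-trips through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param cohort_csv Optional path to an existing cohort CSV; when `NULL`
#'   a synthetic cohort is generated.
#' @param separation_scale Passed to [cohort_config()] for synthetic
#'   cohorts.
#' @param median_models Optional path to a median-model JSON; when `NULL`
#'   models are fitted from the cohort's control group.
#' @param use_builtin_dd Use the built-in published D-dimer median
#'   equation instead of refitting D-dimer from controls.
#' @param log_transform,risk_convention,parse_variant Risk-model options,
#'   see [risk_model_spec()] and [maternal_age_prior()].
#' @param ci_method,prevalence Evaluation options, see [roc_curve()] and
#'   [metrics_at_cutoff()].
#' @param out_dir Output directory for tables and artifacts.
#' @param seed Master integer seed; each stochastic stage derives its own
#'   stream from it (see [run_pipeline()]).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort_csv = NULL, separation_scale = 1,
                       median_models = NULL, use_builtin_dd = FALSE,
                       log_transform = TRUE,
                       risk_convention = "as_printed",
                       parse_variant = "canonical",
                       ci_method = "delong", prevalence = NULL,
                       out_dir = "hdpscreen_run", seed = 1L) {
  structure(
    list(cohort_csv = cohort_csv, separation_scale = separation_scale,
         median_models = median_models, use_builtin_dd = use_builtin_dd,
         log_transform = log_transform, risk_convention = risk_convention,
         parse_variant = parse_variant, ci_method = ci_method,
         prevalence = prevalence, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[!vapply(vals, is.null, TRUE)])
}

# stage-salted seed derivation: inserting a stage does not reshuffle the
# streams of the others; results stay below 2^31
derive_seed <- function(seed, stage) {
  salts <- c(simulate = 101, calibrate = 211, mom = 307, fit = 401,
             score = 503, evaluate = 601)
  stop_if_not(stage %in% names(salts), "unknown stage '%s'", stage)
  (as.integer(seed) * 1009L + salts[[stage]]) %% 2147483647L
}

#' Run the full screening analysis pipeline
#'
#' Composes every stage end to end: obtain a cohort (synthetic or CSV),
#' calibrate median models, convert to MoM, fit and score the ten risk
#' models for the four case definitions (GH, PE, SPE and pooled HDP),
#' evaluate, and write the four summary tables plus per-model ROC
#' coordinates, risk scores, fitted model JSONs and a run manifest into
#' `config$out_dir`.  Identical configuration and seed give byte-identical
#' tables.
#'
#' @param config A [run_config()].
#' @return The run manifest (named list), invisibly also written as
#'   `manifest.json`.
#' @examples
#' \donttest{
#' manifest <- run_pipeline(run_config(out_dir = tempfile(), seed = 7))
#' manifest$n_subjects
#' }
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage: cohort ---------------------------------------------------
  if (is.null(config$cohort_csv)) {
    cc <- cohort_config(seed = derive_seed(config$seed, "simulate"),
                        separation_scale = config$separation_scale)
    cohort <- simulate_cohort(cc)
  } else {
    cohort <- read_cohort(config$cohort_csv)
  }
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  # --- stage: median calibration --------------------------------------
  if (is.null(config$median_models)) {
    models <- fit_all_median_models(cohort)
    if (isTRUE(config$use_builtin_dd)) models$dd <- dd_median_model()
  } else {
    models <- read_median_models(config$median_models)
  }
  write_median_models(models, file.path(config$out_dir, "median_models.json"))

  # --- stage: MoM ------------------------------------------------------
  profiles <- compute_mom(cohort, models)
  utils::write.csv(profiles, file.path(config$out_dir, "mom_profiles.csv"),
                   row.names = FALSE)

  # --- stage: risk models + scoring -----------------------------------
  case_defs <- c("GH", "PE", "SPE", "HDP")
  results_by_case <- stats::setNames(lapply(case_defs, function(cg) {
    run_all_models(profiles, cg,
                   log_transform = config$log_transform,
                   risk_convention = config$risk_convention,
                   parse_variant = config$parse_variant)
  }), case_defs)

  risk_rows <- do.call(rbind, lapply(case_defs, function(cg) {
    do.call(rbind, lapply(names(results_by_case[[cg]]), function(id) {
      res <- results_by_case[[cg]][[id]]
      data.frame(case_group = cg, model_id = as.integer(id),
                 subject_id = res$subject_id, group = res$group,
                 lr = res$lr, risk_age = res$risk_age,
                 risk_hdp = res$risk_hdp, score = res$score,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(risk_rows, file.path(config$out_dir, "risk_scores.csv"),
                   row.names = FALSE)
  for (cg in case_defs) {
    fitted <- lapply(results_by_case[[cg]], function(res)
      attr(res, "case_model"))
    fitted$control <- attr(results_by_case[[cg]][["10"]], "control_model")
    write_group_models(fitted, file.path(
      config$out_dir, sprintf("group_models_%s.json", cg)))
  }

  # --- stage: evaluation ----------------------------------------------
  tables <- summarize_tables(results_by_case, cohort, profiles,
                             ci_method = config$ci_method,
                             prevalence = config$prevalence)
  for (nm in c("table1", "table2", "table3", "table4", "roc_points")) {
    utils::write.csv(tables[[nm]],
                     file.path(config$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hdpscreen")),
    seed = config$seed,
    config = unclass(config),
    n_subjects = nrow(cohort),
    group_sizes = as.list(table(cohort$group)),
    n_evaluation_cells = nrow(tables$table3),
    outputs = c("cohort.csv", "median_models.json", "mom_profiles.csv",
                "risk_scores.csv",
                sprintf("group_models_%s.json", case_defs),
                "table1.csv", "table2.csv", "table3.csv", "table4.csv",
                "roc_points.csv")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(tables = tables, results = results_by_case,
                             cohort = cohort, profiles = profiles)))
}
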