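#' Save a trained model to a JSON checkpoint
#'
#' Single text archive holding the schema tag, model family, configuration,
#' normalizer statistics and all parameter matrices.
#'
#' @param model A `scit_slvm` or `scit_lstm`.
#' @param path Output path (`.json`).
#' @export
model_save <- function(model, path) {
  fam <- if (inherits(model, "scit_slvm")) "slvm" else "lstm"
  obj <- list(schema = "scitseq-checkpoint-1", family = fam,
              config = unclass(model$config),
              norm = unclass(model$norm),
              grid_months = model$grid$months,
              params = lapply(model$params, function(m) {
                list(dim = dim(m), data = as.vector(m))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [model_save()].
#' @return The reconstructed model object.
#' @export
model_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "scitseq-checkpoint-1")) {
    abort("unrecognised checkpoint schema", class = "scitseq_validation_error")
  }
  params <- lapply(obj$params, function(p) matrix(p$data, p$dim[1L], p$dim[2L]))
  cfg_class <- if (obj$family == "slvm") "scit_slvm_config" else "scit_lstm_config"
  cfg <- structure(obj$config, class = cfg_class)
  norm <- structure(obj$norm, class = "scit_normalizer")
  structure(list(config = cfg, params = params, norm = norm,
                 grid = time_grid(obj$grid_months), trace = NULL),
            class = if (obj$family == "slvm") "scit_slvm" else "scit_lstm")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a synthetic cohort: generate, split, train
#' (both model families, optionally per cross-validation fold), one-step and
#' rollout evaluation, the counterfactual treatment contrast, static-feature
#' importance, and the descriptive summary. All randomness fans out from a
#' single root seed via fixed named offsets, recorded with the configuration
#' in `manifest.json`, so re-running with the same manifest reproduces every
#' deterministic output.
#'
#' @param out_dir Artifact directory (created if needed).
#' @param generator A `scit_generator_config` (default: the study-like
#'   preset).
#' @param slvm A `scit_slvm_config` or `NULL` to skip the SLVM.
#' @param lstm A `scit_lstm_config` or `NULL` to skip the baseline.
#' @param seed Root seed.
#' @param test_fraction,k_folds Split parameters.
#' @param cv Train one model per fold (`TRUE`) or a single model on all
#'   training folds (`FALSE`, default — substantially faster).
#' @return Invisibly, a list with the cohort, fitted models, metric tables,
#'   contrast, importance table and the manifest; all tables are also
#'   written as CSV/JSON under `out_dir`.
#' @export
run_pipeline <- function(out_dir, generator = preset_study_like(),
                         slvm = slvm_config(), lstm = lstm_config(),
                         seed = 1L, test_fraction = 0.2, k_folds = 5L,
                         cv = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(generator = seed, split = seed + 1L, slvm = seed + 2L,
                lstm = seed + 3L, sampling = seed + 4L, baseline = seed + 5L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "scitseq_pipeline_error")
    })
  }
  generator$seed <- seeds$generator
  sim <- stage("simulate", generate_cohort(generator))
  cohort <- stage("split", split_cohort(sim$cohort, test_fraction, k_folds,
                                        seed = seeds$split))
  write_cohort(cohort, file.path(out_dir, "visits.csv"),
               file.path(out_dir, "statics.csv"))
  models <- list()
  if (!is.null(slvm)) {
    slvm$seed <- seeds$slvm
    models$slvm <- stage("train-slvm",
                         if (cv) fit_cv_models(cohort, slvm)
                         else slvm_fit(cohort, slvm))
  }
  if (!is.null(lstm)) {
    lstm$seed <- seeds$lstm
    models$lstm <- stage("train-lstm",
                         if (cv) fit_cv_models(cohort, lstm)
                         else lstm_fit(cohort, lstm))
  }
  one_step <- stage("evaluate",
                    run_one_step_experiment(models, cohort,
                                            seed = seeds$sampling))
  rollout <- stage("rollout",
                   run_rollout_experiment(models, cohort,
                                          seed = seeds$sampling))
  readr::write_csv(one_step, file.path(out_dir, "metrics_one_step.csv"))
  readr::write_csv(rollout, file.path(out_dir, "metrics_rollout.csv"))
  baselines <- stage("baselines", random_baselines(cohort,
                                                   seed = seeds$baseline))
  readr::write_csv(baselines, file.path(out_dir, "baselines.csv"))
  contrast <- NULL
  importance <- NULL
  if (!is.null(slvm)) {
    m1 <- if (cv) models$slvm[[1L]] else models$slvm
    contrast <- stage("counterfactual",
                      action_contrast(m1, cohort, seed = seeds$sampling))
    importance <- stage("importance",
                        cohort_importance(m1, cohort))
    readr::write_csv(importance, file.path(out_dir, "importance.csv"))
    jsonlite::write_json(
      list(mean_norm = contrast$mean_norm, mean_raw = contrast$mean_raw,
           ci_norm = contrast$ci_norm,
           dim_mean_norm = as.list(contrast$dim_mean_norm)),
      file.path(out_dir, "counterfactual.json"), auto_unbox = TRUE, digits = NA)
  }
  summary <- stage("summarize", summarize_cohort(cohort))
  readr::write_csv(summary$categorical,
                   file.path(out_dir, "summary_categorical.csv"))
  readr::write_csv(summary$continuous,
                   file.path(out_dir, "summary_continuous.csv"))
  ver <- tryCatch(as.character(utils::packageVersion("scitseq")),
                  error = function(e) "dev")
  gen_plain <- unclass(generator)
  gen_plain$grid <- list(months = generator$grid$months)
  manifest <- list(package_version = ver,
                   seeds = seeds,
                   generator = gen_plain,
                   slvm = if (!is.null(slvm)) unclass(slvm),
                   lstm = if (!is.null(lstm)) unclass(lstm),
                   test_fraction = test_fraction, k_folds = k_folds, cv = cv)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, truth = sim$truth, models = models,
                 one_step = one_step, rollout = rollout,
                 baselines = baselines, contrast = contrast,
                 importance = importance, summary = summary,
                 manifest = manifest))
}
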