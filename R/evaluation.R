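#' Root mean square error
#'
#' @param pred,truth Numeric matrices (or vectors) of identical shape, on
#'   the raw (denormalized) score scale.
#' @param scope `"overall"` (single RMSE over all entries) or
#'   `"per_dimension"` (one RMSE per column).
#' @return A non-negative scalar, or a named vector for `per_dimension`.
#' @export
rmse <- function(pred, truth, scope = c("overall", "per_dimension")) {
  scope <- match.arg(scope)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)) || length(pred) == 0L) {
    abort("`pred` and `truth` must be non-empty and of identical shape",
          class = "scitseq_validation_error")
  }
  if (scope == "overall") {
    sqrt(mean((pred - truth)^2))
  } else {
    out <- sqrt(colMeans((pred - truth)^2))
    if (!is.null(colnames(truth))) names(out) <- colnames(truth)
    out
  }
}

#' Binary classification metrics for adherence prediction
#'
#' Standard confusion-matrix accuracy, precision, recall and F1 with the
#' adherent class (1) as positive. Undefined precision (no predicted
#' positives) or recall (no actual positives) is reported as 0 with a
#' warning; F1 is 0 when precision + recall is 0.
#'
#' @param pred,truth Binary vectors (0/1).
#' @param positive The positive class (default 1, adherent).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(pred, truth, positive = 1) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    abort("`pred` and `truth` must be non-empty and of equal length",
          class = "scitseq_validation_error")
  }
  pp <- pred == positive
  tp_ <- truth == positive
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_); fn <- sum(!pp & tp_)
  accuracy <- mean(pred == truth)
  if (tp + fp == 0L) {
    warn("no predicted positives; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  if (tp + fn == 0L) {
    warn("no actual positives; recall reported as 0")
    recall <- 0
  } else recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Uninformed random baselines
#'
#' Score baseline: predictions drawn uniformly on each dimension's observed
#' range across the cohort; adherence baseline: a fair coin. Both averaged
#' over `n_rep` replicates, per prediction step.
#'
#' @param cohort A `scit_cohort`.
#' @param seed Integer seed.
#' @param patients Patients to evaluate against (default: test set if split,
#'   else all).
#' @param n_rep Monte-Carlo replicates (default 1000).
#' @return A tibble with one row per step `t = 1..T-1`: `rmse_uniform` (for
#'   the score target `x_{t+1}`) and `accuracy_coin` (for `y_t`).
#' @export
random_baselines <- function(cohort, seed = 1L, patients = NULL,
                             n_rep = 1000L) {
  if (is.null(patients)) {
    patients <- if (is.null(cohort$split)) seq_len(n_patients(cohort))
                else test_idx(cohort)
  }
  tt <- cohort$grid$n_steps
  lo <- apply(cohort$x, 3L, min)
  hi <- apply(cohort$x, 3L, max)
  n <- length(patients)
  withr::with_seed(seed, {
    res <- lapply(seq_len(tt - 1L), function(t) {
      truth_x <- cohort$x[patients, t + 1L, , drop = TRUE]
      if (is.null(dim(truth_x))) truth_x <- matrix(truth_x, n)
      truth_y <- cohort$y[patients, t]
      sq <- 0; acc <- 0
      for (r in seq_len(n_rep)) {
        pred <- matrix(runif(n * 11L), n, 11L)
        pred <- sweep(sweep(pred, 2L, hi - lo, "*"), 2L, lo, "+")
        sq <- sq + mean((pred - truth_x)^2)
        acc <- acc + mean(rbinom(n, 1L, 0.5) == truth_y)
      }
      tibble::tibble(step = t, rmse_uniform = sqrt(sq / n_rep),
                     accuracy_coin = acc / n_rep)
    })
    dplyr::bind_rows(res)
  })
}

# internal: metrics for one prediction object at one step
one_step_metrics <- function(pred, cohort, t, patients) {
  n <- length(patients)
  truth_x <- cohort$x[patients, t + 1L, , drop = TRUE]
  if (is.null(dim(truth_x))) truth_x <- matrix(truth_x, n)
  colnames(truth_x) <- score_names
  truth_y <- cohort$y[patients, t]
  cm <- suppressWarnings(classification_metrics(pred$y_label, truth_y))
  per_dim <- rmse(pred$x_mean_raw, truth_x, "per_dimension")
  out <- tibble::tibble(
    step = t,
    rmse = rmse(pred$x_mean_raw, truth_x),
    accuracy = cm[["accuracy"]], precision = cm[["precision"]],
    recall = cm[["recall"]], f1 = cm[["f1"]],
    label_degenerate = all(truth_y == 1))
  for (k in seq_along(score_names)) {
    out[[paste0("rmse_", score_names[k])]] <- per_dim[[k]]
  }
  out
}

resolve_prediction <- function(model, cohort, t, patients, seed) {
  if (is.function(model)) model(cohort, t, patients)
  else predict_one_step(model, cohort, t, patients = patients, seed = seed)
}

#' One-step experiment protocol
#'
#' For every model (optionally one per cross-validation fold) and every step
#' `t = 1..T-1`, predicts `(y_t, x_{t+1})` for the held-out patients from
#' observed history and tabulates RMSE (overall and per score dimension, raw
#' scale) plus the four classification metrics. Step 1 is flagged as
#' label-degenerate: every enrolled patient is adherent over the first
#' interval, so its classification row is trivially perfect.
#'
#' @param models Named list; each element is a trained model, a list of
#'   per-fold trained models, or a function `(cohort, t, patients)`
#'   returning a `scit_prediction` (used to inject oracles in tests).
#' @param cohort A split `scit_cohort`.
#' @param patients Evaluation patients (default: the test set).
#' @param steps Steps to evaluate (default `1..T-1`).
#' @param seed Seed for the probabilistic model's sampling.
#' @return A tidy tibble: one row per model x fold x step.
#' @export
run_one_step_experiment <- function(models, cohort, patients = NULL,
                                    steps = NULL, seed = 1L) {
  if (is.null(patients)) patients <- test_idx(cohort)
  tt <- cohort$grid$n_steps
  if (is.null(steps)) steps <- seq_len(tt - 1L)
  rows <- list()
  for (mn in names(models)) {
    folds <- models[[mn]]
    if (!is.list(folds) || inherits(folds, c("scit_slvm", "scit_lstm")) ||
        is.function(folds)) {
      folds <- list(folds)
    }
    for (fi in seq_along(folds)) {
      for (t in steps) {
        pred <- resolve_prediction(folds[[fi]], cohort, t, patients,
                                   seed + 1000L * fi + t)
        m <- one_step_metrics(pred, cohort, t, patients)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(model = mn, fold = fi), m)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Rollout experiment protocol
#'
#' For each start step `t`, each model forecasts forward through the final
#' visit using only its own fed-back predictions (no future observations),
#' and metrics are tabulated per (start step, target step): RMSE for score
#' targets `u = t+1..T`, classification metrics for adherence targets
#' `i = t..T-1`.
#'
#' @inheritParams run_one_step_experiment
#' @param start_steps Rollout start steps (default `1..T-1`).
#' @return A tidy tibble keyed by model, fold, `start_step`, `target_step`;
#'   score rows carry `rmse`, adherence rows carry the classification
#'   metrics (a target step can carry both).
#' @export
run_rollout_experiment <- function(models, cohort, start_steps = NULL,
                                   patients = NULL, seed = 1L) {
  if (is.null(patients)) patients <- test_idx(cohort)
  tt <- cohort$grid$n_steps
  if (is.null(start_steps)) start_steps <- seq_len(tt - 1L)
  n <- length(patients)
  rows <- list()
  for (mn in names(models)) {
    folds <- models[[mn]]
    if (!is.list(folds) || inherits(folds, c("scit_slvm", "scit_lstm")) ||
        is.function(folds)) {
      folds <- list(folds)
    }
    for (fi in seq_along(folds)) {
      for (t0 in start_steps) {
        ro <- rollout_forecast(folds[[fi]], cohort, t0, patients = patients,
                               seed = seed + 1000L * fi + t0)
        for (u in (t0 + 1L):tt) {
          truth_x <- cohort$x[patients, u, , drop = TRUE]
          if (is.null(dim(truth_x))) truth_x <- matrix(truth_x, n)
          row <- tibble::tibble(model = mn, fold = fi, start_step = t0,
                                target_step = u,
                                rmse = rmse(ro$x_mean_raw[, u, , drop = TRUE],
                                            truth_x),
                                accuracy = NA_real_, precision = NA_real_,
                                recall = NA_real_, f1 = NA_real_)
          if (u - 1L <= tt - 1L && !anyNA(ro$y_label[, u - 1L])) {
            cm <- suppressWarnings(
              classification_metrics(ro$y_label[, u - 1L],
                                     cohort$y[patients, u - 1L]))
            row$accuracy <- cm[["accuracy"]]; row$precision <- cm[["precision"]]
            row$recall <- cm[["recall"]]; row$f1 <- cm[["f1"]]
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Aggregate fold metrics to mean and standard deviation
#'
#' @param metrics A tibble from [run_one_step_experiment()] or
#'   [run_rollout_experiment()].
#' @return A tibble with one row per model x step (x target step), each
#'   numeric metric summarised as `<name>_mean` and `<name>_sd` across folds.
#' @export
aggregate_metrics <- function(metrics) {
  keys <- intersect(c("model", "step", "start_step", "target_step"),
                    names(metrics))
  vals <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                  c("fold", "step", "start_step", "target_step"))
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(vals),
      list(mean = ~mean(.x, na.rm = TRUE),
           sd = ~stats::sd(.x, na.rm = TRUE))), .groups = "drop")
}

#' Train one model per cross-validation fold
#'
#' @param cohort A split `scit_cohort`.
#' @param config A `scit_slvm_config` or `scit_lstm_config`.
#' @param folds Which folds to hold out in turn (default: all).
#' @return A list of trained models, one per held-out fold.
#' @export
fit_cv_models <- function(cohort, config, folds = NULL) {
  if (is.null(folds)) folds <- sort(unique(cohort$split[cohort$split > 0L]))
  fitter <- if (inherits(config, "scit_slvm_config")) slvm_fit else lstm_fit
  lapply(folds, function(f) fitter(cohort, config, holdout_fold = f))
}
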