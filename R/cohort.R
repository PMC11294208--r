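#' @importFrom rlang abort warn
#' @importFrom stats rnorm rbinom runif sd quantile median plogis qlogis
#' @importFrom utils head tail
NULL

#' Symptom and medication score names
#'
#' The eleven per-visit scores: ten visual-analogue-scale (VAS) symptom
#' severities on 0--10 (four nasal, two ocular, four pulmonary) and one
#' cumulative rescue-medication score.
#' @export
score_names <- c("nasal_itching", "sneezing", "rhinorrhea", "nasal_congestion",
                 "ocular_itching", "lacrimation", "shortness_of_breath",
                 "chest_tightness", "cough", "wheezing", "med_score")

#' Static (baseline) feature names
#'
#' Fourteen per-patient covariates recorded at enrolment. The final slot is
#' labelled `reserved`: the data dictionary enumerates thirteen interpretable
#' variables while the feature vector is fourteen-dimensional, so the last
#' dimension carries no clinical meaning and the synthetic generator fills it
#' with uninformative noise.
#' @export
static_names <- c("age", "gender", "distance", "cost_income_ratio",
                  "eos_count", "eos_pct", "delta_nr_pct", "delta_pnif_pct",
                  "total_ige", "sige_derp", "sige_derf",
                  "spt_si_derp", "spt_si_derf", "reserved")

#' Visit time grid
#'
#' The schedule of follow-up visits in months since the start of treatment.
#' The default is the six-visit grid at 0, 4, 12, 18, 24 and 36 months; note
#' the intervals are deliberately uneven (clinical practice), which is why
#' downstream models receive the interval length as an input.
#'
#' @param months Strictly increasing numeric vector of visit times (months).
#' @return An object of class `scit_time_grid` with elements `months`,
#'   `n_steps` and `dt` (interval lengths, months).
#' @export
time_grid <- function(months = c(0, 4, 12, 18, 24, 36)) {
  months <- as.numeric(months)
  if (length(months) < 2L || any(diff(months) <= 0)) {
    abort("`months` must be strictly increasing with at least two visits",
          class = "scitseq_validation_error")
  }
  structure(list(months = months, n_steps = length(months),
                 dt = diff(months)),
            class = "scit_time_grid")
}

#' Construct a cohort object
#'
#' A cohort holds every patient's score trajectory `x` (`N x T x 11`),
#' adherence flags `y` and treatment actions `a` (`N x (T-1)`, binary, with
#' `a == y`), and static features `s` (`N x 14`), all on one shared time
#' grid. `y[, t] = 1` means the patient continued treatment during the
#' interval between visits `t` and `t + 1`; dropout is absorbing.
#'
#' @param grid A `scit_time_grid`.
#' @param ids Character vector of patient identifiers.
#' @param x Numeric array `N x T x 11` of raw-scale scores.
#' @param y,a Numeric matrices `N x (T-1)` of binary adherence / action flags.
#' @param s Numeric matrix `N x 14` of static features.
#' @param split Optional integer vector (`0` = test, `1..K` = training fold).
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `scit_cohort`.
#' @export
new_cohort <- function(grid, ids, x, y, a, s, split = NULL, validate = TRUE) {
  obj <- structure(list(grid = grid, ids = as.character(ids),
                        x = x, y = y, a = a, s = s, split = split),
                   class = "scit_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' Number of patients in a cohort
#' @param cohort A `scit_cohort`.
#' @export
n_patients <- function(cohort) length(cohort$ids)

#' Validate cohort invariants
#'
#' Checks dimensions, score ranges, the all-adherent first interval, the
#' numeric equality of actions and adherence, and that dropout is absorbing
#' (once `y` hits 0 it stays 0). Raises a classed error naming the first
#' offending patient.
#'
#' @param cohort A `scit_cohort`.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  g <- cohort$grid
  n <- length(cohort$ids)
  tt <- g$n_steps
  stop_v <- function(msg) abort(msg, class = "scitseq_validation_error")
  if (!identical(dim(cohort$x), c(n, tt, 11L)) &&
      !identical(dim(cohort$x), as.integer(c(n, tt, 11L)))) {
    stop_v(sprintf("`x` must be %d x %d x 11", n, tt))
  }
  if (!all(dim(cohort$y) == c(n, tt - 1L)) || !all(dim(cohort$a) == c(n, tt - 1L))) {
    stop_v(sprintf("`y` and `a` must be %d x %d", n, tt - 1L))
  }
  if (!all(dim(cohort$s) == c(n, 14L))) stop_v(sprintf("`s` must be %d x 14", n))
  if (anyNA(cohort$x) || anyNA(cohort$y) || anyNA(cohort$a) || anyNA(cohort$s)) {
    stop_v("missing values are not allowed; the record system tracks every patient")
  }
  if (!all(is.finite(cohort$s))) stop_v("static features must be finite")
  sym <- cohort$x[, , 1:10, drop = FALSE]
  if (any(sym < 0 | sym > 10)) {
    bad <- which(apply(sym < 0 | sym > 10, 1, any))[1L]
    stop_v(sprintf("patient %s: symptom VAS scores must lie in [0, 10]",
                   cohort$ids[bad]))
  }
  if (any(cohort$x[, , 11] < 0)) stop_v("medication scores must be non-negative")
  if (!all(cohort$y %in% c(0, 1)) || !all(cohort$a %in% c(0, 1))) {
    stop_v("`y` and `a` must be binary")
  }
  if (any(cohort$y != cohort$a)) {
    bad <- which(apply(cohort$y != cohort$a, 1, any))[1L]
    stop_v(sprintf("patient %s: action and adherence flags disagree",
                   cohort$ids[bad]))
  }
  if (any(cohort$y[, 1L] != 1)) {
    bad <- which(cohort$y[, 1L] != 1)[1L]
    stop_v(sprintf(
      "patient %s: first interval must be adherent (enrolment requires completing buildup)",
      cohort$ids[bad]))
  }
  if (tt > 2L) {
    for (t in 1:(tt - 2L)) {
      viol <- cohort$y[, t] == 0 & cohort$y[, t + 1L] == 1
      if (any(viol)) {
        stop_v(sprintf(
          "patient %s: dropout must be absorbing (y returns to 1 after interval %d)",
          cohort$ids[which(viol)[1L]], t))
      }
    }
  }
  if (!is.null(cohort$split)) {
    if (length(cohort$split) != n || any(cohort$split < 0)) {
      stop_v("`split` must assign every patient to test (0) or a fold (1..K)")
    }
  }
  invisible(cohort)
}

#' Tidy tables from a cohort
#'
#' @param cohort A `scit_cohort`.
#' @return A list of two tibbles: `visits` with columns
#'   `patient_id, step, month, s01..s10, med_score, adherence, action`
#'   (adherence/action are `NA` at the final visit, written blank on disk),
#'   and `statics` with `patient_id, f01..f14`.
#' @export
cohort_tables <- function(cohort) {
  g <- cohort$grid
  n <- n_patients(cohort)
  tt <- g$n_steps
  rows <- expand.grid(step = seq_len(tt), i = seq_len(n))
  xs <- matrix(NA_real_, n * tt, 11L)
  for (k in 1:11) xs[, k] <- as.vector(t(cohort$x[, , k]))
  adh <- cbind(cohort$y, NA_real_)
  act <- cbind(cohort$a, NA_real_)
  visits <- tibble::tibble(
    patient_id = cohort$ids[rows$i],
    step = rows$step,
    month = g$months[rows$step])
  for (k in 1:10) visits[[sprintf("s%02d", k)]] <- xs[, k]
  visits$med_score <- xs[, 11L]
  visits$adherence <- as.vector(t(adh))
  visits$action <- as.vector(t(act))
  statics <- tibble::as_tibble(cohort$s, .name_repair = "minimal")
  names(statics) <- sprintf("f%02d", 1:14)
  statics <- dplyr::bind_cols(tibble::tibble(patient_id = cohort$ids), statics)
  list(visits = visits, statics = statics)
}

#' Write a cohort to CSV
#'
#' @param cohort A `scit_cohort`.
#' @param visits_path,statics_path Output CSV paths.
#' @return Paths, invisibly.
#' @export
write_cohort <- function(cohort, visits_path, statics_path) {
  tabs <- cohort_tables(cohort)
  readr::write_csv(tabs$visits, visits_path, na = "")
  readr::write_csv(tabs$statics, statics_path, na = "")
  invisible(c(visits_path, statics_path))
}

#' Read a cohort from CSV (or in-memory tables)
#'
#' Rows may appear in any order; every patient must have exactly one row per
#' time step and blank adherence/action only at the final step.
#'
#' @param visits A path to the visits CSV or a data frame.
#' @param statics A path to the statics CSV or a data frame.
#' @param grid A `scit_time_grid` (default: the standard six-visit grid).
#' @return A validated `scit_cohort`.
#' @export
read_cohort <- function(visits, statics, grid = time_grid()) {
  if (is.character(visits)) {
    visits <- readr::read_csv(visits, show_col_types = FALSE)
  }
  if (is.character(statics)) {
    statics <- readr::read_csv(statics, show_col_types = FALSE)
  }
  visits <- tibble::as_tibble(visits)
  statics <- tibble::as_tibble(statics)
  tt <- grid$n_steps
  ids <- as.character(statics$patient_id)
  n <- length(ids)
  score_cols <- c(sprintf("s%02d", 1:10), "med_score")
  missing_cols <- setdiff(c("patient_id", "step", score_cols, "adherence", "action"),
                          names(visits))
  if (length(missing_cols)) {
    abort(paste0("visits table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "scitseq_validation_error")
  }
  x <- array(NA_real_, c(n, tt, 11L))
  y <- matrix(NA_real_, n, tt - 1L)
  a <- matrix(NA_real_, n, tt - 1L)
  vid <- as.character(visits$patient_id)
  for (i in seq_len(n)) {
    sub <- visits[vid == ids[i], , drop = FALSE]
    got <- sort(unique(sub$step))
    if (!identical(as.integer(got), seq_len(tt))) {
      miss <- setdiff(seq_len(tt), got)
      abort(sprintf("patient %s: missing time step(s) %s",
                    ids[i], paste(miss, collapse = ", ")),
            class = "scitseq_validation_error")
    }
    sub <- sub[order(sub$step), , drop = FALSE]
    x[i, , ] <- as.matrix(sub[, score_cols])
    y[i, ] <- sub$adherence[seq_len(tt - 1L)]
    a[i, ] <- sub$action[seq_len(tt - 1L)]
  }
  s <- as.matrix(statics[, sprintf("f%02d", 1:14)])
  colnames(s) <- static_names
  new_cohort(grid, ids, x, y, a, s)
}

#' Assign test set and cross-validation folds
#'
#' Holds out `round(test_fraction * N)` patients as a fixed test set and
#' partitions the remainder into `k_folds` near-equal training folds.
#' Deterministic given `seed`.
#'
#' @param cohort A `scit_cohort`.
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param k_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return The cohort with its `split` field set.
#' @export
split_cohort <- function(cohort, test_fraction = 0.2, k_folds = 5L, seed = 1L) {
  n <- n_patients(cohort)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1)", class = "scitseq_validation_error")
  }
  if (k_folds < 2L) abort("`k_folds` must be at least 2",
                          class = "scitseq_validation_error")
  n_test <- round(test_fraction * n)
  if (n_test < 1L || n - n_test < k_folds) {
    abort("cohort too small for the requested partition",
          class = "scitseq_validation_error")
  }
  split <- withr::with_seed(seed, {
    perm <- sample.int(n)
    sp <- integer(n)
    sp[perm[seq_len(n_test)]] <- 0L
    train <- perm[(n_test + 1L):n]
    sp[train] <- rep_len(seq_len(k_folds), length(train))
    sp
  })
  cohort$split <- split
  cohort
}

#' Indices of training patients
#'
#' @param cohort A split `scit_cohort`.
#' @param holdout_fold Optional fold excluded from training (for
#'   cross-validation); `NULL` uses all training folds.
#' @export
train_idx <- function(cohort, holdout_fold = NULL) {
  if (is.null(cohort$split)) abort("cohort has no split; call split_cohort()",
                                   class = "scitseq_validation_error")
  keep <- cohort$split > 0L
  if (!is.null(holdout_fold)) keep <- keep & cohort$split != holdout_fold
  which(keep)
}

#' Indices of test patients
#' @param cohort A split `scit_cohort`.
#' @export
test_idx <- function(cohort) {
  if (is.null(cohort$split)) abort("cohort has no split; call split_cohort()",
                                   class = "scitseq_validation_error")
  which(cohort$split == 0L)
}

#' Fit a zero-mean / unit-sd normalizer on training patients
#'
#' Per-dimension statistics for the eleven scores (pooled over patients and
#' visits) and fourteen static features, computed on training patients only
#' so that no test information leaks into preprocessing. The standard
#' deviation uses the population (1/n) convention, so transformed training
#' data has unit sd exactly. Constant dimensions get sd 1 with a warning.
#'
#' @param cohort A `scit_cohort`.
#' @param patients Integer indices of the patients to compute statistics on;
#'   defaults to the cohort's training patients if split, else all.
#' @return An object of class `scit_normalizer`.
#' @export
fit_normalizer <- function(cohort, patients = NULL) {
  if (is.null(patients)) {
    patients <- if (is.null(cohort$split)) seq_len(n_patients(cohort))
                else train_idx(cohort)
  }
  xs <- cohort$x[patients, , , drop = FALSE]
  xmat <- matrix(NA_real_, length(patients) * cohort$grid$n_steps, 11L)
  for (k in 1:11) xmat[, k] <- as.vector(xs[, , k])
  smat <- cohort$s[patients, , drop = FALSE]
  pop_sd <- function(m) {
    mu <- colMeans(m)
    sdv <- sqrt(colMeans(sweep(m, 2L, mu)^2))
    if (any(sdv <= 0)) {
      warn("constant dimension(s) found; their sd is set to 1")
      sdv[sdv <= 0] <- 1
    }
    list(mean = mu, sd = sdv)
  }
  xs_st <- pop_sd(xmat)
  ss_st <- pop_sd(smat)
  structure(list(x_mean = xs_st$mean, x_sd = xs_st$sd,
                 s_mean = ss_st$mean, s_sd = ss_st$sd),
            class = "scit_normalizer")
}

#' Apply or invert a normalizer
#'
#' @param norm A `scit_normalizer`.
#' @param m A matrix whose columns are score dimensions (`which = "x"`) or
#'   static features (`which = "s"`).
#' @param which `"x"` or `"s"`.
#' @return The transformed matrix.
#' @export
normalize_mat <- function(norm, m, which = c("x", "s")) {
  which <- match.arg(which)
  mu <- norm[[paste0(which, "_mean")]]
  sdv <- norm[[paste0(which, "_sd")]]
  sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
}

#' @rdname normalize_mat
#' @export
denormalize_mat <- function(norm, m, which = c("x", "s")) {
  which <- match.arg(which)
  mu <- norm[[paste0(which, "_mean")]]
  sdv <- norm[[paste0(which, "_sd")]]
  sweep(sweep(m, 2L, sdv, "*"), 2L, mu, "+")
}

# internal: normalized per-step x matrices and s matrix for a patient subset
cohort_norm_arrays <- function(cohort, norm, patients) {
  tt <- cohort$grid$n_steps
  xs <- lapply(seq_len(tt), function(t) {
    m <- cohort$x[patients, t, , drop = FALSE]
    normalize_mat(norm, matrix(m, length(patients), 11L), "x")
  })
  s <- normalize_mat(norm, cohort$s[patients, , drop = FALSE], "s")
  list(x = xs, s = s,
       y = cohort$y[patients, , drop = FALSE],
       a = cohort$a[patients, , drop = FALSE])
}

#' @export
print.scit_cohort <- function(x, ...) {
  cat(sprintf("<scit_cohort> %d patients, %d visits at months %s\n",
              n_patients(x), x$grid$n_steps,
              paste(x$grid$months, collapse = "/")))
  nonadh <- mean(x$y[, ncol(x$y)] == 0)
  cat(sprintf("  cumulative non-adherence by final interval: %.1f%%\n",
              100 * nonadh))
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d test, folds {%s}\n", sum(x$split == 0L),
                paste(table(x$split[x$split > 0L]), collapse = ",")))
  }
  invisible(x)
}
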