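#' Integrated-gradients attribution
#'
#' Path-integral attribution of a scalar differentiable function `f` of a
#' feature vector, along the straight line from `baseline` to `s`, using an
#' `m`-point right-Riemann approximation:
#' `IG_i = (s_i - s'_i) * (1/m) * sum_k df(s' + (k/m)(s - s'))/ds_i`.
#' Satisfies the completeness axiom `sum_i IG_i = f(s) - f(baseline)` up to
#' a discretisation error that shrinks as `m` grows, and is exact for
#' linear `f` at any `m`.
#'
#' @param f Scalar function of a numeric vector.
#' @param s Feature vector to attribute.
#' @param baseline Reference vector (same length as `s`).
#' @param m Number of path steps (default 64).
#' @param grad_f Optional gradient function returning `length(s)` partials;
#'   central finite differences are used when absent.
#' @return Numeric vector of attributions, one per feature.
#' @export
integrated_gradients <- function(f, s, baseline, m = 64L, grad_f = NULL) {
  if (length(s) != length(baseline)) {
    abort("`s` and `baseline` must have equal length",
          class = "scitseq_validation_error")
  }
  if (m < 1L) abort("`m` must be at least 1", class = "scitseq_validation_error")
  test_val <- f(s)
  if (length(test_val) != 1L || !is.numeric(test_val)) {
    abort("`f` must return a numeric scalar", class = "scitseq_validation_error")
  }
  if (is.null(grad_f)) {
    h <- 1e-5
    grad_f <- function(p) {
      vapply(seq_along(p), function(i) {
        e <- replace(numeric(length(p)), i, h)
        (f(p + e) - f(p - e)) / (2 * h)
      }, numeric(1))
    }
  }
  diff <- s - baseline
  acc <- numeric(length(s))
  for (k in seq_len(m)) {
    acc <- acc + grad_f(baseline + (k / m) * diff)
  }
  diff * acc / m
}

# Gradient of the SLVM adherence probability at step `t` with respect to the
# normalized static features, with the patient's own scores and actions held
# fixed. Uses deterministic mean propagation of the filtering posterior so
# the attributed function is a smooth deterministic map of s.
slvm_adherence_grad <- function(model, d, t, s_norm) {
  cfg <- model$config
  L <- cfg$latent_dim
  n <- nrow(s_norm)
  dts <- dt_feats(model$grid)
  tape <- new_tape()
  lp <- leaf_params(tape, model$params)
  s_nd <- ad_leaf(tape, s_norm)
  z <- NULL
  for (tt_ in seq_len(t)) {
    if (tt_ == 1L) {
      raw <- mlp_forward(tape, lp, "q0",
                         ad_cbind(tape, list(ad_const(tape, d$x[[1L]]), s_nd)))
    } else {
      parts <- list(z, ad_const(tape, d$x[[tt_]]),
                    ad_const(tape, matrix(d$a[, tt_ - 1L], n, 1L)))
      if (cfg$interval_feature) {
        parts <- c(parts, list(ad_const(tape, matrix(dts[tt_ - 1L], n, 1L))))
      }
      raw <- mlp_forward(tape, lp, "qt", ad_cbind(tape, c(parts, list(s_nd))))
    }
    z <- ad_cols(tape, raw, 1:L)   # posterior mean
  }
  p <- ad_sigmoid(tape, mlp_forward(tape, lp, "dy", z))
  out <- ad_sum(tape, p)   # each row's probability depends only on its own s
  ad_backward(tape, out)
  list(grad = s_nd$grad, prob = drop(p$value))
}

#' Cohort-level feature importance for adherence predictions
#'
#' Integrated-gradients attribution of the model's adherence probability at
#' step `t` to the fourteen static features, per patient, aggregated across
#' the cohort by mean absolute attribution and ranked. The attributed
#' function propagates the filtering posterior means (no sampling), holding
#' each patient's observed scores and actions fixed; the baseline is the
#' all-zeros vector in normalized feature space, i.e. the training-cohort
#' mean patient.
#'
#' @param model A trained `scit_slvm`.
#' @param cohort A `scit_cohort`.
#' @param t Target step for the adherence probability (default 2, the first
#'   step whose labels are not degenerate).
#' @param patients Patient indices (default: test set if split, else all).
#' @param m Path steps for the Riemann approximation (default 64).
#' @param baseline Optional baseline matrix or vector in normalized feature
#'   space (default zeros).
#' @return A tibble `feature, mean_abs_ig, rank` (rank 1 = most important),
#'   with the `N x 14` per-patient attribution matrix in attribute
#'   `per_patient` and the endpoint probabilities in `prob`/`prob_baseline`.
#' @export
cohort_importance <- function(model, cohort, t = 2L, patients = NULL,
                              m = 64L, baseline = NULL) {
  if (!inherits(model, "scit_slvm")) {
    abort("feature importance is defined for the latent state-space model",
          class = "scitseq_capability_error")
  }
  if (is.null(model$trace)) {
    abort("model is untrained; fit it before computing importances",
          class = "scitseq_validation_error")
  }
  tt <- cohort$grid$n_steps
  if (t < 1L || t > tt - 1L) {
    abort(sprintf("`t` must be in 1..%d", tt - 1L),
          class = "scitseq_validation_error")
  }
  if (is.null(patients)) {
    patients <- if (is.null(cohort$split)) seq_len(n_patients(cohort))
                else test_idx(cohort)
  }
  d <- cohort_norm_arrays(cohort, model$norm, patients)
  n <- length(patients)
  s_obs <- d$s
  base <- if (is.null(baseline)) matrix(0, n, 14L)
          else matrix(baseline, n, 14L, byrow = is.vector(baseline))
  diff <- s_obs - base
  acc <- matrix(0, n, 14L)
  for (k in seq_len(m)) {
    gr <- slvm_adherence_grad(model, d, t, base + (k / m) * diff)
    acc <- acc + gr$grad
  }
  ig <- diff * acc / m
  colnames(ig) <- static_names
  p_end <- slvm_adherence_grad(model, d, t, s_obs)$prob
  p_base <- slvm_adherence_grad(model, d, t, base)$prob
  imp <- colMeans(abs(ig))
  out <- tibble::tibble(feature = static_names, mean_abs_ig = unname(imp))
  out <- out[order(-out$mean_abs_ig), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "per_patient") <- ig
  attr(out, "prob") <- p_end
  attr(out, "prob_baseline") <- p_base
  out
}
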