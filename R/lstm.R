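#' Configuration for the LSTM baseline
#'
#' A single-layer LSTM consumes, at each visit `t`, the current scores
#' `x_t`, the previous adherence flag `y_{t-1}` (with `y_0 := 1`, every
#' patient enters under treatment), the static features `s` and the interval
#' length `dt_t`, and predicts the next scores `x_{t+1}` and the current
#' adherence `y_t` in parallel through two linear heads. Training minimises
#' mean squared error on normalized scores plus `lambda` times binary
#' cross-entropy on adherence. The model is fully deterministic at
#' prediction time; its uncertainty comes only from cross-validation folds.
#'
#' @param hidden_size LSTM hidden width (default 64).
#' @param layers Number of recurrent layers (only 1 is supported).
#' @param learning_rate Adam step size (default 5e-3).
#' @param epochs Training epochs (default 300).
#' @param lambda Weight on the adherence loss term (default 1).
#' @param batch_size Minibatch size; `Inf` trains full-batch.
#' @param seed Integer seed.
#' @return An object of class `scit_lstm_config`.
#' @export
lstm_config <- function(hidden_size = 64L, layers = 1L, learning_rate = 5e-3,
                        epochs = 300L, lambda = 1, batch_size = Inf,
                        seed = 1L) {
  if (hidden_size < 1L || lambda < 0) {
    abort("invalid LSTM configuration", class = "scitseq_validation_error")
  }
  if (layers != 1L) {
    abort("only single-layer LSTMs are supported",
          class = "scitseq_validation_error")
  }
  structure(list(hidden_size = as.integer(hidden_size), layers = 1L,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 lambda = lambda, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "scit_lstm_config")
}

LSTM_D_IN <- 11L + 1L + 14L + 1L   # x_t, y_{t-1}, s, dt

lstm_init_params <- function(cfg) {
  H <- cfg$hidden_size
  p <- list(
    lstm_W = matrix(rnorm(LSTM_D_IN * 4L * H, sd = 1 / sqrt(LSTM_D_IN)),
                    LSTM_D_IN, 4L * H),
    lstm_U = matrix(rnorm(H * 4L * H, sd = 1 / sqrt(H)), H, 4L * H),
    lstm_b = matrix(0, 1L, 4L * H),
    ox_W = matrix(rnorm(H * 11L, sd = 1 / sqrt(H)), H, 11L),
    ox_b = matrix(0, 1L, 11L),
    oy_W = matrix(rnorm(H, sd = 1 / sqrt(H)), H, 1L),
    oy_b = matrix(0, 1L, 1L))
  # forget-gate bias at 1 (standard initialisation for gradient flow)
  p$lstm_b[1L, (H + 1L):(2L * H)] <- 1
  p
}

# one LSTM cell step on the tape
lstm_cell_graph <- function(tape, lp, H, x_nd, h, cc) {
  gates <- ad_add(tape, ad_add(tape, ad_mm(tape, x_nd, lp$lstm_W),
                               ad_mm(tape, h, lp$lstm_U)), lp$lstm_b)
  i <- ad_sigmoid(tape, ad_cols(tape, gates, 1:H))
  f <- ad_sigmoid(tape, ad_cols(tape, gates, (H + 1L):(2L * H)))
  g <- ad_tanh(tape, ad_cols(tape, gates, (2L * H + 1L):(3L * H)))
  o <- ad_sigmoid(tape, ad_cols(tape, gates, (3L * H + 1L):(4L * H)))
  cc <- ad_add(tape, ad_mul(tape, f, cc), ad_mul(tape, i, g))
  h <- ad_mul(tape, o, ad_tanh(tape, cc))
  list(h = h, c = cc)
}

# off-tape cell step
lstm_cell_eval <- function(p, H, x, h, cc) {
  gates <- sweep(x %*% p$lstm_W + h %*% p$lstm_U, 2L, p$lstm_b[1L, ], "+")
  i <- plogis(gates[, 1:H, drop = FALSE])
  f <- plogis(gates[, (H + 1L):(2L * H), drop = FALSE])
  g <- tanh(gates[, (2L * H + 1L):(3L * H), drop = FALSE])
  o <- plogis(gates[, (3L * H + 1L):(4L * H), drop = FALSE])
  cc <- f * cc + i * g
  h <- o * tanh(cc)
  list(h = h, c = cc)
}

lstm_step_input <- function(x_t, y_prev, s, dt) {
  cbind(x_t, y_prev, s, dt)
}

#' Fit the LSTM baseline
#'
#' @param cohort A `scit_cohort`.
#' @param config A [lstm_config()].
#' @param holdout_fold Optional training fold to exclude.
#' @param verbose Print progress every 50 epochs.
#' @return A trained `scit_lstm` with a per-epoch loss `trace`.
#' @export
lstm_fit <- function(cohort, config = lstm_config(), holdout_fold = NULL,
                     verbose = FALSE) {
  patients <- if (is.null(cohort$split)) seq_len(n_patients(cohort))
              else train_idx(cohort, holdout_fold)
  norm <- fit_normalizer(cohort, patients)
  cfg <- config
  d <- cohort_norm_arrays(cohort, norm, patients)
  d$dt <- dt_feats(cohort$grid)
  n <- length(patients)
  tt <- cohort$grid$n_steps
  H <- cfg$hidden_size
  bs <- if (is.finite(cfg$batch_size)) as.integer(cfg$batch_size) else n
  withr::with_seed(cfg$seed, {
    params <- lstm_init_params(cfg)
    opt <- adam_state(params)
    trace <- matrix(NA_real_, cfg$epochs, 3L,
                    dimnames = list(NULL, c("loss", "mse_x", "bce_y")))
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      tot <- c(0, 0); tot_n <- 0L
      for (b0 in seq(1L, n, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1L, n)]
        nb <- length(idx)
        tape <- new_tape()
        lp <- leaf_params(tape, params)
        h <- ad_const(tape, matrix(0, nb, H))
        cc <- ad_const(tape, matrix(0, nb, H))
        loss_x <- NULL; loss_y <- NULL
        add_nd <- function(a, b) if (is.null(a)) b else ad_add(tape, a, b)
        y_prev <- rep(1, nb)
        for (t in seq_len(tt - 1L)) {
          xin <- lstm_step_input(d$x[[t]][idx, , drop = FALSE],
                                 y_prev, d$s[idx, , drop = FALSE], d$dt[t])
          st <- lstm_cell_graph(tape, lp, H, ad_const(tape, xin), h, cc)
          h <- st$h; cc <- st$c
          xhat <- ad_linear(tape, h, lp$ox_W, lp$ox_b)
          ylog <- ad_linear(tape, h, lp$oy_W, lp$oy_b)
          err <- ad_sub(tape, xhat, ad_const(tape, d$x[[t + 1L]][idx, , drop = FALSE]))
          loss_x <- add_nd(loss_x, ad_sum(tape, ad_square(tape, err)))
          bce <- ad_scale(tape,
                          ad_bernoulli_loglik_sum(
                            tape, matrix(d$y[idx, t], nb, 1L), ylog), -1)
          loss_y <- add_nd(loss_y, bce)
          y_prev <- d$y[idx, t]
        }
        loss <- ad_scale(tape,
                         ad_add(tape, loss_x, ad_scale(tape, loss_y, cfg$lambda)),
                         1 / nb)
        if (!is.finite(loss$value[1L])) {
          abort(sprintf("LSTM training diverged at epoch %d", ep),
                class = "scitseq_numeric_error")
        }
        ad_backward(tape, loss)
        st <- adam_step(params, collect_grads(lp), opt, lr = cfg$learning_rate)
        params <- st$params; opt <- st$state
        tot <- tot + c(loss_x$value[1L], loss_y$value[1L]); tot_n <- tot_n + nb
      }
      trace[ep, ] <- c((tot[1L] + cfg$lambda * tot[2L]) / tot_n, tot / tot_n)
      if (verbose && ep %% 50L == 0L) {
        message(sprintf("epoch %d  loss %.4f", ep, trace[ep, "loss"]))
      }
    }
    structure(list(config = cfg, params = params, norm = norm,
                   grid = cohort$grid,
                   trace = tibble::as_tibble(as.data.frame(trace))),
              class = "scit_lstm")
  })
}

#' Initialise an untrained LSTM baseline
#'
#' @inheritParams lstm_fit
#' @param norm Optional pre-fitted normalizer.
#' @return An untrained `scit_lstm` (its predictions reflect random
#'   initialisation; useful for no-op-training checks).
#' @export
lstm_init <- function(cohort, config = lstm_config(), norm = NULL) {
  if (is.null(norm)) norm <- fit_normalizer(cohort)
  params <- withr::with_seed(config$seed, lstm_init_params(config))
  structure(list(config = config, params = params, norm = norm,
                 grid = cohort$grid, trace = NULL),
            class = "scit_lstm")
}

# run the LSTM over steps 1..upto with observed inputs; returns final state
# plus the head outputs at step `upto`
lstm_run_observed <- function(model, d, idx_all, upto) {
  p <- model$params
  H <- model$config$hidden_size
  n <- nrow(d$s)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  y_prev <- rep(1, n)
  for (t in seq_len(upto)) {
    xin <- lstm_step_input(d$x[[t]], y_prev, d$s, d$dt[t])
    st <- lstm_cell_eval(p, H, xin, h, cc)
    h <- st$h; cc <- st$c
    if (t <= ncol(d$y)) y_prev <- d$y[, t]
  }
  list(h = h, c = cc,
       xhat = sweep(h %*% p$ox_W, 2L, p$ox_b[1L, ], "+"),
       ylogit = drop(h %*% p$oy_W) + p$oy_b[1L, 1L])
}

#' LSTM predictions (one-step or rollout)
#'
#' In `one_step` mode the network consumes the observed history `x_{1:t}`,
#' `y_{1:t-1}` and returns `y_t` and `x_{t+1}`. In `rollout` mode it feeds
#' its own predictions back autoregressively from step `t` through the final
#' visit: predicted scores re-enter as inputs, and the fed-back adherence
#' flag is thresholded at 0.5 (absorbing, matching the binary training
#' inputs).
#'
#' @param model A trained `scit_lstm`.
#' @param cohort A `scit_cohort`.
#' @param t Prediction (or rollout start) step, `1 <= t <= T-1`.
#' @param mode `"one_step"` or `"rollout"`.
#' @param patients Patient indices (default all).
#' @return `one_step`: a `scit_prediction` (zero sampling spread — the model
#'   is deterministic). `rollout`: a `scit_rollout` with `y_prob` and score
#'   arrays filled from step `t` onward.
#' @export
predict_lstm <- function(model, cohort, t, mode = c("one_step", "rollout"),
                         patients = NULL) {
  mode <- match.arg(mode)
  tt <- cohort$grid$n_steps
  if (t < 1L || t > tt - 1L) {
    abort(sprintf("`t` must be in 1..%d", tt - 1L),
          class = "scitseq_validation_error")
  }
  if (is.null(patients)) patients <- seq_len(n_patients(cohort))
  d <- cohort_norm_arrays(cohort, model$norm, patients)
  d$dt <- dt_feats(model$grid)
  n <- length(patients)
  p <- model$params
  H <- model$config$hidden_size
  if (mode == "one_step") {
    out <- lstm_run_observed(model, d, patients, t)
    y_prob <- plogis(out$ylogit)
    x_norm <- out$xhat
    return(structure(list(patients = patients, t = t, n_samples = 1L,
                          y_prob = y_prob, y_sd = rep(0, n),
                          y_label = as.integer(y_prob >= 0.5),
                          x_mean_raw = denormalize_mat(model$norm, x_norm, "x"),
                          x_sd_raw = matrix(0, n, 11L),
                          x_mean_norm = x_norm,
                          x_sd_norm = matrix(0, n, 11L)),
                     class = "scit_prediction"))
  }
  # rollout: observed through step t, then autoregressive feedback
  y_prob <- matrix(NA_real_, n, tt - 1L)
  x_mean_raw <- array(NA_real_, c(n, tt, 11L))
  x_mean_norm <- array(NA_real_, c(n, tt, 11L))
  out <- lstm_run_observed(model, d, patients, t)
  h <- out$h; cc <- out$c
  yp <- plogis(out$ylogit)
  xn <- out$xhat
  # absorbing feedback state starts from the last observed adherence flag
  y_fed <- if (t >= 2L) d$y[, t - 1L] else rep(1, n)
  for (i in t:(tt - 1L)) {
    y_prob[, i] <- yp
    x_mean_norm[, i + 1L, ] <- xn
    x_mean_raw[, i + 1L, ] <- denormalize_mat(model$norm, xn, "x")
    if (i == tt - 1L) break
    y_fed <- y_fed * as.numeric(yp >= 0.5)
    xin <- lstm_step_input(xn, y_fed, d$s, d$dt[i + 1L])
    st <- lstm_cell_eval(p, H, xin, h, cc)
    h <- st$h; cc <- st$c
    xn <- sweep(h %*% p$ox_W, 2L, p$ox_b[1L, ], "+")
    yp <- plogis(drop(h %*% p$oy_W) + p$oy_b[1L, 1L])
  }
  structure(list(patients = patients, start_t = t, n_samples = 1L,
                 y_prob = y_prob,
                 y_sd = matrix(0, n, tt - 1L),
                 y_label = ifelse(is.na(y_prob), NA_integer_,
                                  as.integer(y_prob >= 0.5)),
                 x_mean_raw = x_mean_raw,
                 x_sd_raw = array(0, c(n, tt, 11L)),
                 x_mean_norm = x_mean_norm,
                 x_sd_norm = array(0, c(n, tt, 11L))),
            class = "scit_rollout")
}

# --- shared generics used by the evaluation protocols ---------------------

#' One-step prediction generic
#'
#' Dispatches to [slvm_predict_one_step()] or [predict_lstm()] so the
#' evaluation protocols can treat both model families uniformly.
#'
#' @param model A trained `scit_slvm` or `scit_lstm`.
#' @param cohort A `scit_cohort`.
#' @param t Prediction step.
#' @param ... Passed to the method (`patients`, `n_samples`, `seed`).
#' @export
predict_one_step <- function(model, cohort, t, ...) {
  UseMethod("predict_one_step")
}

#' @export
predict_one_step.scit_slvm <- function(model, cohort, t, ...) {
  slvm_predict_one_step(model, cohort, t, ...)
}

#' @export
predict_one_step.scit_lstm <- function(model, cohort, t, patients = NULL, ...) {
  predict_lstm(model, cohort, t, mode = "one_step", patients = patients)
}

#' Rollout forecasting generic
#'
#' @inheritParams predict_one_step
#' @param start_t Rollout start step.
#' @export
rollout_forecast <- function(model, cohort, start_t, ...) {
  UseMethod("rollout_forecast")
}

#' @export
rollout_forecast.scit_slvm <- function(model, cohort, start_t, ...) {
  slvm_rollout(model, cohort, start_t, ...)
}

#' @export
rollout_forecast.scit_lstm <- function(model, cohort, start_t,
                                       patients = NULL, ...) {
  predict_lstm(model, cohort, start_t, mode = "rollout", patients = patients)
}
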