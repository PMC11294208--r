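#' Configuration for the sequential latent-variable model
#'
#' The SLVM is a Gaussian state-space model over a latent patient state
#' `z_t` with action and static-covariate conditioning: an initial prior
#' `p(z_1 | s)`, a transition prior `p(z_{t+1} | z_t, a_t, dt_t, s)`, a
#' diagonal-Gaussian score decoder `p(x_t | z_t)` with learned variance, a
#' Bernoulli adherence decoder `p(y_t | z_t)`, and a filtering posterior
#' `q(z_1 | x_1, s)`, `q(z_{t+1} | z_t, x_{t+1}, a_t, dt_t, s)`. All
#' conditionals are one-hidden-layer tanh networks; training maximises the
#' evidence lower bound with single-sample reparameterized estimates.
#'
#' @param latent_dim Latent state dimension (default 16).
#' @param hidden_width Hidden-layer width of every network (default 64).
#' @param kl_weight Weight `beta` on the KL term of the ELBO (default 1).
#' @param learning_rate Adam step size (default 5e-3).
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size; `Inf` (default) trains full-batch.
#' @param n_latent_samples Latent samples used at prediction time to form
#'   means and sampling spreads (default 100).
#' @param interval_feature Append the interval length `dt` (months / 12) to
#'   transition and posterior inputs (default `TRUE`); the visit grid is
#'   uneven, and the 12-month final interval behaves differently.
#' @param seed Integer seed for initialisation and training noise.
#' @return An object of class `scit_slvm_config`.
#' @export
slvm_config <- function(latent_dim = 16L, hidden_width = 64L, kl_weight = 1,
                        learning_rate = 5e-3, epochs = 300L,
                        batch_size = Inf, n_latent_samples = 100L,
                        interval_feature = TRUE, seed = 1L) {
  if (latent_dim < 1L || kl_weight < 0 || n_latent_samples < 1L) {
    abort("invalid SLVM configuration", class = "scitseq_validation_error")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_width = as.integer(hidden_width),
                 kl_weight = kl_weight, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 n_latent_samples = as.integer(n_latent_samples),
                 interval_feature = isTRUE(interval_feature),
                 seed = as.integer(seed)),
            class = "scit_slvm_config")
}

# soft bound on log-variances, in (-B, B); keeps training stable without a
# hard clamp that would break differentiability
LV_BOUND <- 5

lv_squash <- function(tape, raw) {
  ad_scale(tape, ad_tanh(tape, ad_scale(tape, raw, 1 / LV_BOUND)), LV_BOUND)
}

lv_squash_num <- function(raw) LV_BOUND * tanh(raw / LV_BOUND)

slvm_dims <- function(cfg) {
  L <- cfg$latent_dim
  di <- if (cfg$interval_feature) 1L else 0L
  list(L = L,
       p0_in = 14L, pt_in = L + 1L + di + 14L,
       q0_in = 11L + 14L, qt_in = L + 11L + 1L + di + 14L)
}

slvm_init_params <- function(cfg) {
  d <- slvm_dims(cfg)
  H <- cfg$hidden_width
  p <- c(init_mlp(d$p0_in, H, 2L * d$L, "p0"),
         init_mlp(d$pt_in, H, 2L * d$L, "pt"),
         init_mlp(d$q0_in, H, 2L * d$L, "q0"),
         init_mlp(d$qt_in, H, 2L * d$L, "qt"),
         init_mlp(d$L, H, 11L, "dx"),
         init_mlp(d$L, H, 1L, "dy"))
  p$dx_logvar <- matrix(0, 1L, 11L)
  p
}

#' Initialise an untrained SLVM
#'
#' @param cohort A `scit_cohort` used to fit the normalizer (training
#'   patients if the cohort is split).
#' @param config A [slvm_config()].
#' @param norm Optional pre-fitted `scit_normalizer`.
#' @return An object of class `scit_slvm`.
#' @export
slvm_init <- function(cohort, config = slvm_config(), norm = NULL) {
  if (is.null(norm)) norm <- fit_normalizer(cohort)
  params <- withr::with_seed(config$seed, slvm_init_params(config))
  structure(list(config = config, params = params, norm = norm,
                 grid = cohort$grid, trace = NULL),
            class = "scit_slvm")
}

# scaled interval lengths used as conditioning features
dt_feats <- function(grid) grid$dt / 12

# Build the ELBO graph for a normalized batch. `eps` is an N x T x L array
# of standard-normal reparameterization noise. Returns the output node plus
# component nodes.
slvm_elbo_graph <- function(tape, lp, cfg, data, eps) {
  d <- slvm_dims(cfg)
  tt <- length(data$x)
  n <- nrow(data$s)
  s_nd <- if (is_ad_node(data$s_node)) data$s_node else ad_const(tape, data$s)
  dts <- data$dt
  recon_x <- NULL; recon_y <- NULL; kl <- NULL
  add_nd <- function(a, b) if (is.null(a)) b else ad_add(tape, a, b)
  z_prev <- NULL
  for (t in seq_len(tt)) {
    if (t == 1L) {
      prior_raw <- mlp_forward(tape, lp, "p0", s_nd)
      q_in <- ad_cbind(tape, list(ad_const(tape, data$x[[1L]]), s_nd))
      q_raw <- mlp_forward(tape, lp, "q0", q_in)
    } else {
      a_prev <- ad_const(tape, matrix(data$a[, t - 1L], n, 1L))
      parts <- list(z_prev, a_prev)
      if (cfg$interval_feature) {
        parts <- c(parts, list(ad_const(tape, matrix(dts[t - 1L], n, 1L))))
      }
      prior_raw <- mlp_forward(tape, lp, "pt",
                               ad_cbind(tape, c(parts, list(s_nd))))
      q_raw <- mlp_forward(tape, lp, "qt",
                           ad_cbind(tape, c(list(z_prev),
                                            list(ad_const(tape, data$x[[t]])),
                                            parts[-1L], list(s_nd))))
    }
    mu_p <- ad_cols(tape, prior_raw, 1:d$L)
    lv_p <- lv_squash(tape, ad_cols(tape, prior_raw, (d$L + 1L):(2L * d$L)))
    mu_q <- ad_cols(tape, q_raw, 1:d$L)
    lv_q <- lv_squash(tape, ad_cols(tape, q_raw, (d$L + 1L):(2L * d$L)))
    kl <- add_nd(kl, ad_kl_diag_sum(tape, mu_q, lv_q, mu_p, lv_p))
    e_t <- ad_const(tape, matrix(eps[, t, ], n, d$L))
    z_t <- ad_add(tape, mu_q,
                  ad_mul(tape, ad_exp(tape, ad_scale(tape, lv_q, 0.5)), e_t))
    mu_x <- mlp_forward(tape, lp, "dx", z_t)
    lv_x <- lv_squash(tape, lp$dx_logvar)
    recon_x <- add_nd(recon_x,
                      ad_gauss_loglik_sum(tape, data$x[[t]], mu_x, lv_x))
    if (t <= tt - 1L) {
      logit_y <- mlp_forward(tape, lp, "dy", z_t)
      recon_y <- add_nd(recon_y,
                        ad_bernoulli_loglik_sum(
                          tape, matrix(data$y[, t], n, 1L), logit_y))
    }
    z_prev <- z_t
  }
  elbo <- ad_add(tape, ad_add(tape, recon_x, recon_y),
                 ad_scale(tape, kl, -cfg$kl_weight))
  list(elbo = elbo, recon_x = recon_x, recon_y = recon_y, kl = kl)
}

#' Evidence lower bound of an SLVM on a set of patients
#'
#' Single-sample reparameterized estimate, summed over patients and time
#' steps: score reconstruction + adherence reconstruction - beta * KL.
#'
#' @param model A `scit_slvm`.
#' @param cohort A `scit_cohort`.
#' @param patients Indices of the patients to evaluate (default all).
#' @param eps Optional `N x T x L` array of standard-normal noise; supply to
#'   make the estimate deterministic. Drawn internally otherwise.
#' @param seed Optional seed for the internal noise draw.
#' @return A list with `elbo` and the component sums `recon_x`, `recon_y`,
#'   `kl` (all scalars).
#' @export
slvm_elbo <- function(model, cohort, patients = NULL, eps = NULL, seed = NULL) {
  if (is.null(patients)) patients <- seq_len(n_patients(cohort))
  cfg <- model$config
  data <- cohort_norm_arrays(cohort, model$norm, patients)
  data$dt <- dt_feats(cohort$grid)
  n <- length(patients)
  tt <- cohort$grid$n_steps
  if (is.null(eps)) {
    eps <- if (is.null(seed)) {
      array(rnorm(n * tt * cfg$latent_dim), c(n, tt, cfg$latent_dim))
    } else {
      withr::with_seed(seed,
        array(rnorm(n * tt * cfg$latent_dim), c(n, tt, cfg$latent_dim)))
    }
  }
  tape <- new_tape()
  lp <- leaf_params(tape, model$params)
  gr <- slvm_elbo_graph(tape, lp, cfg, data, eps)
  out <- list(elbo = gr$elbo$value[1L], recon_x = gr$recon_x$value[1L],
              recon_y = gr$recon_y$value[1L], kl = gr$kl$value[1L])
  for (nm in names(out)) {
    if (!is.finite(out[[nm]])) {
      abort(sprintf("non-finite ELBO term `%s`", nm),
            class = "scitseq_numeric_error")
    }
  }
  out
}

#' Fit the sequential latent-variable model
#'
#' Maximises the ELBO with Adam on the cohort's training patients (all
#' patients if the cohort has no split). Deterministic given the config seed.
#'
#' @param cohort A `scit_cohort`.
#' @param config A [slvm_config()].
#' @param holdout_fold Optional training fold to exclude (cross-validation).
#' @param verbose Print progress every 50 epochs.
#' @return A trained `scit_slvm` carrying a per-epoch loss `trace`
#'   (negative mean ELBO per patient, with component breakdown).
#' @export
slvm_fit <- function(cohort, config = slvm_config(), holdout_fold = NULL,
                     verbose = FALSE) {
  patients <- if (is.null(cohort$split)) seq_len(n_patients(cohort))
              else train_idx(cohort, holdout_fold)
  norm <- fit_normalizer(cohort, patients)
  cfg <- config
  data_all <- cohort_norm_arrays(cohort, norm, patients)
  data_all$dt <- dt_feats(cohort$grid)
  n <- length(patients)
  tt <- cohort$grid$n_steps
  L <- cfg$latent_dim
  bs <- if (is.finite(cfg$batch_size)) as.integer(cfg$batch_size) else n
  model <- withr::with_seed(cfg$seed, {
    params <- slvm_init_params(cfg)
    opt <- adam_state(params)
    trace <- matrix(NA_real_, cfg$epochs, 4L,
                    dimnames = list(NULL, c("loss", "recon_x", "recon_y", "kl")))
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      ep_tot <- c(0, 0, 0); ep_n <- 0L
      for (b0 in seq(1L, n, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1L, n)]
        nb <- length(idx)
        batch <- list(x = lapply(data_all$x, function(m) m[idx, , drop = FALSE]),
                      s = data_all$s[idx, , drop = FALSE],
                      y = data_all$y[idx, , drop = FALSE],
                      a = data_all$a[idx, , drop = FALSE],
                      dt = data_all$dt)
        eps <- array(rnorm(nb * tt * L), c(nb, tt, L))
        tape <- new_tape()
        lp <- leaf_params(tape, params)
        gr <- slvm_elbo_graph(tape, lp, cfg, batch, eps)
        loss <- ad_scale(tape, gr$elbo, -1 / nb)
        if (!is.finite(loss$value[1L])) {
          comps <- c(recon_x = gr$recon_x$value[1L],
                     recon_y = gr$recon_y$value[1L], kl = gr$kl$value[1L])
          bad <- names(comps)[!is.finite(comps)]
          abort(sprintf("SLVM training diverged at epoch %d (non-finite %s)",
                        ep, paste(bad, collapse = ", ")),
                class = "scitseq_numeric_error")
        }
        ad_backward(tape, loss)
        st <- adam_step(params, collect_grads(lp), opt, lr = cfg$learning_rate)
        params <- st$params; opt <- st$state
        ep_tot <- ep_tot + c(gr$recon_x$value[1L], gr$recon_y$value[1L],
                             gr$kl$value[1L])
        ep_n <- ep_n + nb
      }
      trace[ep, ] <- c(-(ep_tot[1L] + ep_tot[2L] - cfg$kl_weight * ep_tot[3L]) / ep_n,
                       ep_tot / ep_n)
      if (verbose && ep %% 50L == 0L) {
        message(sprintf("epoch %d  loss %.4f", ep, trace[ep, "loss"]))
      }
    }
    structure(list(config = cfg, params = params, norm = norm,
                   grid = cohort$grid,
                   trace = tibble::as_tibble(as.data.frame(trace))),
              class = "scit_slvm")
  })
  model
}

# --- filtering and prediction (off-tape, vectorized over particles) -------

# Split a raw 2L-wide net output into (mu, squashed logvar)
split_gauss <- function(raw, L) {
  list(mu = raw[, 1:L, drop = FALSE],
       lv = lv_squash_num(raw[, (L + 1L):(2L * L), drop = FALSE]))
}

# Run the filtering posterior through step `upto`, with `n_samples`
# particles per patient. xs: list of T normalized N x 11 matrices; a: N x
# (T-1); s: normalized N x 14. Returns an (N*S) x L matrix of z_upto
# particles (patient-major: particle blocks are contiguous per patient).
slvm_filter_particles <- function(model, xs, a, s, upto, n_samples) {
  cfg <- model$config
  p <- model$params
  L <- cfg$latent_dim
  n <- nrow(s)
  ns <- n * n_samples
  rep_idx <- rep(seq_len(n), each = n_samples)
  s_rep <- s[rep_idx, , drop = FALSE]
  dts <- dt_feats(model$grid)
  z <- NULL
  for (t in seq_len(upto)) {
    if (t == 1L) {
      raw <- mlp_eval(p, "q0", cbind(xs[[1L]][rep_idx, , drop = FALSE], s_rep))
    } else {
      a_prev <- matrix(a[rep_idx, t - 1L], ns, 1L)
      inp <- cbind(z, xs[[t]][rep_idx, , drop = FALSE], a_prev)
      if (cfg$interval_feature) inp <- cbind(inp, dts[t - 1L])
      raw <- mlp_eval(p, "qt", cbind(inp, s_rep))
    }
    g <- split_gauss(raw, L)
    z <- g$mu + exp(0.5 * g$lv) * matrix(rnorm(ns * L), ns, L)
  }
  z
}

# one transition-prior step for particles; a_vec length N*S, dt scalar
slvm_prior_step <- function(model, z, a_vec, dt, s_rep, eps = NULL) {
  cfg <- model$config
  L <- cfg$latent_dim
  inp <- cbind(z, matrix(a_vec, length(a_vec), 1L))
  if (cfg$interval_feature) inp <- cbind(inp, dt)
  g <- split_gauss(mlp_eval(model$params, "pt", cbind(inp, s_rep)), L)
  if (is.null(eps)) eps <- matrix(rnorm(nrow(z) * L), nrow(z), L)
  g$mu + exp(0.5 * g$lv) * eps
}

particle_summary <- function(v, n, n_samples) {
  # v: (N*S) x k particle-level values, patient-major (particles contiguous)
  k <- ncol(v)
  mean_m <- matrix(NA_real_, n, k)
  sd_m <- matrix(0, n, k)
  for (j in seq_len(k)) {
    m <- matrix(v[, j], nrow = n_samples)   # columns are patients
    mu <- colMeans(m)
    mean_m[, j] <- mu
    if (n_samples > 1L) {
      sd_m[, j] <- sqrt(colSums(sweep(m, 2L, mu)^2) / (n_samples - 1L))
    }
  }
  list(mean = mean_m, sd = sd_m)
}

#' One-step-ahead SLVM prediction
#'
#' Filters the posterior through step `t` using the observed scores
#' `x_{1:t}` and actions `a_{1:t-1}`, then predicts the adherence flag `y_t`
#' (decoded from `n_latent_samples` posterior particles of `z_t`) and the
#' next scores `x_{t+1}` (each particle propagated through the transition
#' prior with the *observed* action `a_t`, then decoded).
#'
#' @param model A trained `scit_slvm`.
#' @param cohort A `scit_cohort`.
#' @param t Prediction step, `1 <= t <= T-1`.
#' @param patients Indices of patients to predict for (default all).
#' @param n_samples Latent sample count (default from config).
#' @param seed Optional seed for the sampling noise.
#' @return An object of class `scit_prediction`: a list with `y_prob`,
#'   `y_sd`, `y_label` (threshold 0.5, ties adherent), `x_mean_raw`,
#'   `x_sd_raw` (`N x 11`, VAS scale), their normalized-scale companions,
#'   and bookkeeping fields.
#' @export
slvm_predict_one_step <- function(model, cohort, t, patients = NULL,
                                  n_samples = NULL, seed = NULL) {
  tt <- cohort$grid$n_steps
  if (t < 1L || t > tt - 1L) {
    abort(sprintf("`t` must be in 1..%d", tt - 1L),
          class = "scitseq_validation_error")
  }
  if (is.null(patients)) patients <- seq_len(n_patients(cohort))
  if (is.null(n_samples)) n_samples <- model$config$n_latent_samples
  run <- function() {
    d <- cohort_norm_arrays(cohort, model$norm, patients)
    n <- length(patients)
    rep_idx <- rep(seq_len(n), each = n_samples)
    z_t <- slvm_filter_particles(model, d$x, d$a, d$s, t, n_samples)
    p_y <- plogis(mlp_eval(model$params, "dy", z_t))
    a_true <- d$a[rep_idx, t]
    z_next <- slvm_prior_step(model, z_t, a_true, dt_feats(model$grid)[t],
                              d$s[rep_idx, , drop = FALSE])
    x_mu <- mlp_eval(model$params, "dx", z_next)
    ys <- particle_summary(p_y, n, n_samples)
    xs <- particle_summary(x_mu, n, n_samples)
    x_mean_raw <- denormalize_mat(model$norm, xs$mean, "x")
    x_sd_raw <- sweep(xs$sd, 2L, model$norm$x_sd, "*")
    structure(list(patients = patients, t = t, n_samples = n_samples,
                   y_prob = drop(ys$mean), y_sd = drop(ys$sd),
                   y_label = as.integer(drop(ys$mean) >= 0.5),
                   x_mean_raw = x_mean_raw, x_sd_raw = x_sd_raw,
                   x_mean_norm = xs$mean, x_sd_norm = xs$sd),
              class = "scit_prediction")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Multi-step SLVM rollout
#'
#' Filters the posterior through `start_t`, then forecasts forward through
#' the final visit using only the transition prior: at each future step the
#' injected action is the model's own thresholded adherence prediction
#' (per particle, and absorbing — once a particle predicts discontinuation
#' its subsequent actions stay 0), so no future observations are consumed.
#'
#' @param model A trained `scit_slvm`.
#' @param cohort A `scit_cohort`.
#' @param start_t Rollout start step, `1 <= start_t <= T-1`.
#' @param patients Patient indices (default all).
#' @param n_samples Particle count (default from config).
#' @param seed Optional seed.
#' @param forced_actions Optional matrix (`N x (T - start_t)`) of actions to
#'   inject instead of the model's own adherence predictions (used by the
#'   counterfactual contrast).
#' @param eps Optional pre-drawn noise list (common-random-number support):
#'   element `trans` is a list over future steps of `(N*S) x L` matrices.
#' @param z_init Optional pre-filtered `(N * n_samples) x L` particle matrix
#'   for `z_{start_t}`; skips the filtering pass (used to share one filtered
#'   state across counterfactual arms).
#' @return A list with `y_prob`, `y_sd` (`N x (T-1)` matrices, columns
#'   `start_t..T-1` filled), `x_mean_raw`, `x_sd_raw`, `x_mean_norm`,
#'   `x_sd_norm` (`N x T x 11` arrays, steps `start_t+1..T` filled), class
#'   `scit_rollout`.
#' @export
slvm_rollout <- function(model, cohort, start_t, patients = NULL,
                         n_samples = NULL, seed = NULL,
                         forced_actions = NULL, eps = NULL, z_init = NULL) {
  tt <- cohort$grid$n_steps
  if (start_t < 1L || start_t > tt - 1L) {
    abort(sprintf("`start_t` must be in 1..%d", tt - 1L),
          class = "scitseq_validation_error")
  }
  if (is.null(patients)) patients <- seq_len(n_patients(cohort))
  if (is.null(n_samples)) n_samples <- model$config$n_latent_samples
  run <- function() {
    d <- cohort_norm_arrays(cohort, model$norm, patients)
    n <- length(patients)
    ns <- n * n_samples
    rep_idx <- rep(seq_len(n), each = n_samples)
    s_rep <- d$s[rep_idx, , drop = FALSE]
    dts <- dt_feats(model$grid)
    z <- if (is.null(z_init)) {
      slvm_filter_particles(model, d$x, d$a, d$s, start_t, n_samples)
    } else z_init
    y_prob <- matrix(NA_real_, n, tt - 1L)
    y_sd <- matrix(NA_real_, n, tt - 1L)
    x_mean_raw <- array(NA_real_, c(n, tt, 11L))
    x_sd_raw <- array(NA_real_, c(n, tt, 11L))
    x_mean_norm <- array(NA_real_, c(n, tt, 11L))
    x_sd_norm <- array(NA_real_, c(n, tt, 11L))
    a_alive <- rep(1, ns)   # absorbing action state per particle
    for (i in start_t:(tt - 1L)) {
      p_y <- plogis(drop(mlp_eval(model$params, "dy", z)))
      ys <- particle_summary(matrix(p_y, ns, 1L), n, n_samples)
      y_prob[, i] <- ys$mean
      y_sd[, i] <- ys$sd
      if (is.null(forced_actions)) {
        a_inj <- a_alive * as.numeric(p_y >= 0.5)
        a_alive <- a_inj
      } else {
        a_inj <- rep(forced_actions[, i - start_t + 1L], each = n_samples)
      }
      e_t <- if (!is.null(eps)) eps$trans[[i - start_t + 1L]] else NULL
      z <- slvm_prior_step(model, z, a_inj, dts[i], s_rep, eps = e_t)
      x_mu <- mlp_eval(model$params, "dx", z)
      xs <- particle_summary(x_mu, n, n_samples)
      x_mean_raw[, i + 1L, ] <- denormalize_mat(model$norm, xs$mean, "x")
      x_sd_raw[, i + 1L, ] <- sweep(xs$sd, 2L, model$norm$x_sd, "*")
      x_mean_norm[, i + 1L, ] <- xs$mean
      x_sd_norm[, i + 1L, ] <- xs$sd
    }
    structure(list(patients = patients, start_t = start_t,
                   n_samples = n_samples,
                   y_prob = y_prob, y_sd = y_sd,
                   y_label = ifelse(is.na(y_prob), NA_integer_,
                                    as.integer(y_prob >= 0.5)),
                   x_mean_raw = x_mean_raw, x_sd_raw = x_sd_raw,
                   x_mean_norm = x_mean_norm, x_sd_norm = x_sd_norm),
              class = "scit_rollout")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
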