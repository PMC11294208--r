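test_that("the ELBO matches a closed-form oracle on 1-D toy instances", {
  for (seed in 1:5) {
    co <- toy_t2_cohort(seed)
    cfg <- slvm_config(latent_dim = 1L, hidden_width = 3L,
                       kl_weight = 0.7, seed = seed)
    m <- suppressWarnings(slvm_init(co, cfg))
    eps <- withr::with_seed(seed + 50, array(rnorm(2 * 2), c(2, 2, 1)))
    got <- slvm_elbo(m, co, eps = eps)
    want1 <- oracle_elbo_t2(m, co, eps[1, , , drop = FALSE], 0.7)
    co1 <- co; co1$x <- co$x[2, , , drop = FALSE]
    want2 <- oracle_elbo_t2(
      list(params = m$params, norm = m$norm),
      new_cohort(co$grid, "B", co$x[2, , , drop = FALSE],
                 matrix(1, 1, 1), matrix(1, 1, 1),
                 co$s[2, , drop = FALSE]),
      eps[2, , , drop = FALSE], 0.7)
    expect_lt(abs(got$elbo - (want1$elbo + want2$elbo)), 1e-5)
    expect_lt(abs(got$kl - (want1$kl + want2$kl)), 1e-5)
    expect_lt(abs(got$recon_y - (want1$recon_y + want2$recon_y)), 1e-5)
  }
})

test_that("with kl_weight 0 the ELBO is the reconstruction sum alone", {
  co <- toy_t2_cohort(3)
  cfg <- slvm_config(latent_dim = 2L, hidden_width = 4L, kl_weight = 0,
                     seed = 3L)
  m <- suppressWarnings(slvm_init(co, cfg))
  got <- slvm_elbo(m, co, seed = 1L)
  expect_equal(got$elbo, got$recon_x + got$recon_y)
  expect_gte(got$kl, 0)
})

test_that("a zero-epoch fit equals its initialisation", {
  co <- split_cohort(tiny_cohort(n = 20L, seed = 4L), 0.2, 2L, seed = 1L)
  cfg <- quick_slvm_config(epochs = 0L, seed = 5L)
  m0 <- slvm_fit(co, cfg)
  mi <- slvm_init(co, cfg, norm = fit_normalizer(co))
  expect_equal(m0$params, mi$params)
  p0 <- slvm_predict_one_step(m0, co, 2, n_samples = 5, seed = 11)
  pi <- slvm_predict_one_step(mi, co, 2, n_samples = 5, seed = 11)
  expect_equal(p0$y_prob, pi$y_prob)
  expect_equal(p0$x_mean_raw, pi$x_mean_raw)
})

test_that("predictions are seed-deterministic and respect their contracts", {
  co <- split_cohort(tiny_cohort(n = 25L, seed = 8L), 0.2, 2L, seed = 1L)
  m <- slvm_fit(co, quick_slvm_config(epochs = 15L, seed = 2L))
  a <- slvm_predict_one_step(m, co, 3, n_samples = 1, seed = 7)
  b <- slvm_predict_one_step(m, co, 3, n_samples = 1, seed = 7)
  expect_identical(a$y_prob, b$y_prob)
  expect_identical(a$x_mean_raw, b$x_mean_raw)
  big <- slvm_predict_one_step(m, co, 2, n_samples = 40, seed = 7)
  expect_true(all(big$y_prob >= 0 & big$y_prob <= 1))
  expect_true(all(big$y_sd >= 0))
  expect_true(all(big$x_sd_raw >= 0))
  expect_error(slvm_predict_one_step(m, co, 6),
               class = "scitseq_validation_error")
})

test_that("training reconstructs noise-free dynamics to within 0.5 VAS", {
  cfgG <- generator_config(n_patients = 150L, noise_std = 0,
                           treatment_effect = 0.08, rebound_rate = 0.2,
                           seed = 4L)
  co <- generate_cohort(cfgG)$cohort
  m <- slvm_fit(co, slvm_config(latent_dim = 8L, hidden_width = 32L,
                                epochs = 200L, learning_rate = 1e-2,
                                seed = 4L))
  d <- scitseq:::cohort_norm_arrays(co, m$norm, seq_len(150L))
  errs <- withr::with_seed(1L, vapply(1:6, function(t) {
    z <- scitseq:::slvm_filter_particles(m, d$x, d$a, d$s, t, 30L)
    sm <- scitseq:::particle_summary(
      scitseq:::mlp_eval(m$params, "dx", z), 150L, 30L)
    rmse(denormalize_mat(m$norm, sm$mean, "x"), co$x[, t, ])
  }, numeric(1)))
  expect_lt(max(errs), 0.5)
})

test_that("the smoothed training loss is non-increasing over the last half", {
  finals <- vapply(1:5, function(seed) {
    co <- generate_cohort(preset_study_like(80L, seed = seed))$cohort
    m <- slvm_fit(co, quick_slvm_config(epochs = 60L, seed = seed))
    sm <- stats::filter(m$trace$loss, rep(1 / 10, 10), sides = 1)
    sm <- sm[!is.na(sm)]
    half <- sm[(length(sm) %/% 2):length(sm)]
    # allow minuscule stochastic wiggle in the smoothed curve
    max(diff(half))
  }, numeric(1))
  expect_lt(mean(finals), 0.05)
})

test_that("KL stays non-negative on every training step", {
  co <- generate_cohort(preset_study_like(60L, seed = 9L))$cohort
  m <- slvm_fit(co, quick_slvm_config(epochs = 30L, seed = 9L))
  expect_true(all(m$trace$kl >= 0))
})

test_that("a rollout started at the last interval matches one-step output", {
  co <- split_cohort(tiny_cohort(n = 30L, seed = 12L), 0.2, 2L, seed = 1L)
  m <- slvm_fit(co, quick_slvm_config(epochs = 20L, seed = 3L))
  te <- test_idx(co)
  one <- slvm_predict_one_step(m, co, 5, patients = te, n_samples = 10,
                               seed = 77)
  ro <- slvm_rollout(m, co, 5, patients = te, n_samples = 10, seed = 77)
  # the adherence head sees the identical filtered particles
  expect_equal(ro$y_prob[, 5], one$y_prob, tolerance = 1e-12)
  # score forecasts coincide whenever the injected action equals the truth
  agree <- (one$y_prob >= 0.5) == (co$a[te, 5] == 1)
  if (any(agree)) {
    expect_equal(ro$x_mean_norm[agree, 6, ],
                 one$x_mean_norm[agree, ], tolerance = 0.75)
  }
})

test_that("predicted non-adherence shuts off all subsequent injected actions", {
  co <- split_cohort(tiny_cohort(n = 20L, seed = 13L), 0.2, 2L, seed = 1L)
  m <- slvm_fit(co, quick_slvm_config(epochs = 10L, seed = 3L))
  # force the adherence head to always predict dropout
  m$params$dy_W2[] <- 0
  m$params$dy_b2[] <- -5
  te <- test_idx(co)
  n <- length(te)
  L <- m$config$latent_dim
  d <- scitseq:::cohort_norm_arrays(co, m$norm, te)
  z0 <- withr::with_seed(5L,
    scitseq:::slvm_filter_particles(m, d$x, d$a, d$s, 2L, 4L))
  eps <- withr::with_seed(6L, list(trans = lapply(1:4, function(i) {
    matrix(rnorm(n * 4L * L), n * 4L, L)
  })))
  auto <- slvm_rollout(m, co, 2L, patients = te, n_samples = 4L,
                       eps = eps, z_init = z0)
  forced0 <- slvm_rollout(m, co, 2L, patients = te, n_samples = 4L,
                          forced_actions = matrix(0, n, 4L),
                          eps = eps, z_init = z0)
  expect_equal(auto$x_mean_norm, forced0$x_mean_norm, tolerance = 1e-12)
})

test_that("Monte-Carlo spread of predicted means shrinks like 1/sqrt(n)", {
  co <- split_cohort(tiny_cohort(n = 20L, seed = 14L), 0.2, 2L, seed = 1L)
  m <- slvm_fit(co, quick_slvm_config(epochs = 20L, seed = 3L))
  spread <- vapply(c(10L, 100L, 1000L), function(ns) {
    reps <- vapply(1:20, function(r) {
      slvm_predict_one_step(m, co, 2, patients = 1L, n_samples = ns,
                            seed = 1000L + r)$y_prob
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  expect_gt(spread[1], spread[2])
  expect_gt(spread[2], spread[3])
  # ratio across a 100-fold sample increase should be near 10
  expect_gt(spread[1] / spread[3], 3)
  expect_lt(spread[1] / spread[3], 33)
})
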