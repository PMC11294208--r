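test_that("rmse matches hand computation", {
  set.seed(21)
  truth <- matrix(runif(40 * 11, 0, 10), 40, 11)
  expect_equal(rmse(truth, truth), 0)
  expect_equal(rmse(truth + 1, truth), 1)
  pred <- truth + matrix(rnorm(40 * 11), 40, 11)
  expect_equal(rmse(pred, truth), sqrt(mean((pred - truth)^2)),
               tolerance = 1e-12)
  per <- rmse(pred, truth, "per_dimension")
  expect_equal(unname(per), sqrt(colMeans((pred - truth)^2)),
               tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), class = "scitseq_validation_error")
})

test_that("classification metrics agree with a confusion-matrix oracle", {
  # the degenerate first interval: everyone adherent, everyone predicted so
  all1 <- classification_metrics(rep(1, 41), rep(1, 41))
  expect_equal(unname(all1), c(1, 1, 1, 1))
  hand <- classification_metrics(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unname(hand), c(0.5, 0.5, 0.5, 0.5))
  set.seed(22)
  for (r in 1:100) {
    truth <- rbinom(200, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(200, 1, runif(1, 0.2, 0.8))
    got <- suppressWarnings(classification_metrics(pred, truth))
    tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + rc > 0) 2 * p * rc / (p + rc) else 0
    expect_identical(unname(got), c((tp + tn) / 200, p, rc, f1))
  }
  expect_warning(classification_metrics(c(0, 0), c(1, 0)), "precision")
})

test_that("random baselines converge to their closed forms", {
  # truth 0 everywhere at evaluated steps; observed range [0, 10]
  co <- tiny_cohort(n = 30L, seed = 3L)
  co$x[] <- 0
  co$x[1, 1, ] <- 10            # pins the observed range at [0, 10]
  bl <- random_baselines(co, seed = 5L, patients = 1:30, n_rep = 400L)
  expect_equal(bl$rmse_uniform, rep(10 / sqrt(3), 5), tolerance = 0.02)
  # zero-width range: constant truth, constant predictions
  co2 <- tiny_cohort(n = 10L, seed = 3L)
  co2$x[] <- 4
  bl2 <- random_baselines(co2, seed = 5L, patients = 1:10, n_rep = 50L)
  expect_equal(bl2$rmse_uniform, rep(0, 5))
  # fair coin accuracy near 1/2 against balanced labels needs no model
  expect_true(all(abs(bl$accuracy_coin - 0.5) < 0.05))
})

oracle_prediction <- function(cohort) {
  function(co, t, patients) {
    n <- length(patients)
    structure(list(patients = patients, t = t, n_samples = 1L,
                   y_prob = cohort$y[patients, t],
                   y_sd = rep(0, n),
                   y_label = cohort$y[patients, t],
                   x_mean_raw = matrix(cohort$x[patients, t + 1, ], n, 11),
                   x_sd_raw = matrix(0, n, 11),
                   x_mean_norm = matrix(0, n, 11),
                   x_sd_norm = matrix(0, n, 11)),
              class = "scit_prediction")
  }
}

test_that("an injected oracle model scores perfectly at every step", {
  co <- split_cohort(tiny_cohort(n = 30L, seed = 11L), 0.2, 3L, seed = 2L)
  tbl <- run_one_step_experiment(list(oracle = oracle_prediction(co)), co)
  expect_equal(nrow(tbl), 5L)
  expect_true(all(tbl$rmse == 0))
  expect_true(all(tbl$accuracy == 1 & tbl$precision == 1 &
                    tbl$recall == 1 & tbl$f1 == 1))
  expect_true(tbl$label_degenerate[tbl$step == 1])
})

test_that("the experiment table has one row per model, fold and step", {
  co <- split_cohort(tiny_cohort(n = 30L, seed = 11L), 0.2, 3L, seed = 2L)
  orc <- oracle_prediction(co)
  tbl <- run_one_step_experiment(
    list(m1 = list(orc, orc, orc), m2 = orc), co)
  expect_equal(nrow(tbl), (3L + 1L) * 5L)
  agg <- aggregate_metrics(tbl)
  expect_equal(nrow(agg), 2L * 5L)
  # aggregation is the plain mean / sd over folds
  sub <- tbl[tbl$model == "m1" & tbl$step == 2, ]
  expect_equal(agg$rmse_mean[agg$model == "m1" & agg$step == 2],
               mean(sub$rmse))
  expect_equal(agg$rmse_sd[agg$model == "m1" & agg$step == 2], sd(sub$rmse))
})

test_that("rollout metrics cover every start/target pair", {
  co <- split_cohort(tiny_cohort(n = 25L, seed = 15L), 0.2, 2L, seed = 2L)
  m <- lstm_fit(co, quick_lstm_config(epochs = 5L, seed = 1L))
  tbl <- run_rollout_experiment(list(lstm = m), co)
  for (t0 in 1:5) {
    expect_setequal(tbl$target_step[tbl$start_step == t0], (t0 + 1):6)
  }
  expect_true(all(tbl$rmse >= 0))
  # the start-step row duplicates the one-step prediction at that step
  one <- run_one_step_experiment(list(lstm = m), co)
  for (t0 in 1:5) {
    expect_equal(tbl$accuracy[tbl$start_step == t0 & tbl$target_step == t0 + 1],
                 one$accuracy[one$step == t0])
  }
})
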