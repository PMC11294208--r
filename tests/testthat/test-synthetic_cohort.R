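# Independent re-simulation of the generator's documented mechanism, used
# as a Monte-Carlo oracle for the dropout fraction. Written directly from
# the severity-decay / logistic-hazard description, patient by patient.
oracle_dropout_fraction <- function(config, n = 100000L, seed = 12345L) {
  g <- config$grid
  withr::with_seed(seed, {
    s <- scitseq:::draw_statics(n)
    sev <- cbind(pmin(pmax(rnorm(n, 5.5, 1.8), 0.3), 9.5),
                 pmin(pmax(rnorm(n, 4.0, 1.8), 0), 9),
                 pmin(rgamma(n, shape = 1.2, scale = 1.2), 8))
    tot <- function(m) 4 * m[, 1] + 2 * m[, 2] + 4 * m[, 3]
    tot0 <- tot(sev)
    alive <- rep(TRUE, n)
    for (t in 1:(g$n_steps - 1L)) {
      if (t >= 2L) {
        z <- scitseq:::hazard_covariates(s[, "distance"],
                                         s[, "cost_income_ratio"],
                                         tot(sev), tot0, g$months[t])
        p <- plogis(config$hazard_intercepts[t - 1L] +
                      drop(z %*% config$hazard_weights))
        alive <- alive & (runif(n) >= p)
      }
      dt <- g$dt[t]
      sev <- ifelse(alive, 1, 0) * sev * exp(-config$treatment_effect * dt) +
        ifelse(alive, 0, 1) * pmin(sev + config$rebound_rate * dt, 10)
    }
    mean(!alive)
  })
}

test_that("generation is bitwise-deterministic given seed and config", {
  cfg <- generator_config(n_patients = 30L, seed = 9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$x, b$cohort$x)
  expect_identical(a$cohort$y, b$cohort$y)
  expect_identical(a$cohort$s, b$cohort$s)
  expect_identical(a$truth$severity, b$truth$severity)
})

test_that("degenerate dynamics yield constant trajectories", {
  cfg <- generator_config(n_patients = 10L, noise_std = 0,
                          treatment_effect = 0, rebound_rate = 0,
                          hazard_intercepts = rep(-50, 4), seed = 2L)
  gt <- generate_cohort(cfg)
  for (t in 2:6) expect_equal(gt$cohort$x[, t, ], gt$cohort$x[, 1, ])
  expect_true(all(gt$cohort$y == 1))
})

test_that("strongly negative intercepts disable dropout entirely", {
  cfg <- generator_config(n_patients = 200L,
                          hazard_intercepts = rep(-50, 4), seed = 3L)
  gt <- generate_cohort(cfg)
  expect_true(all(gt$cohort$y == 1))
})

test_that("every draw satisfies the patient-record invariants", {
  for (seed in 1:5) {
    gt <- generate_cohort(generator_config(n_patients = 50L, seed = seed))
    expect_silent(validate_cohort(gt$cohort))
    expect_true(all(gt$cohort$y[, 1] == 1))
    expect_identical(gt$cohort$a, gt$cohort$y)
    expect_true(all(is.na(gt$truth$hazard[, 1])))
  }
})

test_that("empirical dropout matches the Monte-Carlo hazard oracle", {
  cfg <- generator_config(n_patients = 2000L, seed = 7L)
  gt <- generate_cohort(cfg)
  emp <- mean(gt$cohort$y[, 5] == 0)
  orc <- oracle_dropout_fraction(cfg, n = 100000L)
  expect_lt(abs(emp - orc), 0.03)
})

test_that("heavier distance weighting increases dropout among far patients", {
  base <- generator_config(n_patients = 3000L, seed = 21L)
  heavy <- base
  heavy$hazard_weights["distance"] <- base$hazard_weights["distance"] + 1.5
  a <- generate_cohort(base)    # common random numbers: same seed and
  b <- generate_cohort(heavy)   # identical draw sequence up to the hazard
  far_a <- a$cohort$s[, "distance"] > 10
  far_b <- b$cohort$s[, "distance"] > 10
  expect_identical(far_a, far_b)
  expect_gt(mean(b$cohort$y[far_b, 5] == 0), mean(a$cohort$y[far_a, 5] == 0))
})

test_that("the study-like preset reproduces the cohort's withdrawal shape", {
  fr_total <- numeric(50)
  fr_last <- numeric(50)
  for (s in 1:50) {
    gt <- generate_cohort(preset_study_like(seed = s))
    y <- gt$cohort$y
    events <- sapply(2:5, function(t) sum(y[, t - 1] == 1 & y[, t] == 0))
    fr_total[s] <- mean(y[, 5] == 0)
    fr_last[s] <- events[4] / max(sum(events), 1)
    expect_true(all(y[, 1] == 1))
  }
  expect_gt(mean(fr_total), 0.58)
  expect_lt(mean(fr_total), 0.70)
  expect_gt(mean(fr_last), 0.35)
  expect_lt(mean(fr_last), 0.50)
})
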