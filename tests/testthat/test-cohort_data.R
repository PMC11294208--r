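test_that("a well-formed two-patient table pair reads into a cohort", {
  tabs <- two_patient_tables()
  co <- read_cohort(tabs$visits, tabs$statics, tabs$grid)
  expect_s3_class(co, "scit_cohort")
  expect_equal(n_patients(co), 2L)
  expect_equal(co$grid$n_steps, 6L)
  expect_equal(co$y[, 1], c(1, 1))
  expect_equal(co$s[1, "gender"], c(gender = 1))
})

test_that("validation rejects broken records with informative errors", {
  tabs <- two_patient_tables()
  # non-absorbing dropout
  v <- tabs$visits
  v$adherence[v$patient_id == "A"] <- c(1, 1, 0, 1, 0, NA)
  v$action <- v$adherence
  expect_error(read_cohort(v, tabs$statics, tabs$grid),
               "absorbing", class = "scitseq_validation_error")
  # y / a mismatch
  v <- tabs$visits
  v$action[2] <- 0
  expect_error(read_cohort(v, tabs$statics, tabs$grid),
               "disagree", class = "scitseq_validation_error")
  # missing step names the patient and the step
  v <- tabs$visits[-3, ]
  expect_error(read_cohort(v, tabs$statics, tabs$grid),
               "patient A.*step.*3", class = "scitseq_validation_error")
  # first interval must be adherent
  v <- tabs$visits
  v$adherence[v$patient_id == "B" & v$step == 1] <- 0
  v$action <- v$adherence
  expect_error(read_cohort(v, tabs$statics, tabs$grid),
               "first interval", class = "scitseq_validation_error")
})

test_that("random corruptions of y are always rejected", {
  co <- tiny_cohort(n = 12L, seed = 7L)
  set.seed(99)
  rejected <- 0L
  for (r in 1:40) {
    bad <- co
    i <- sample.int(12L, 1)
    mode <- sample(1:3, 1)
    if (mode == 1L) {                      # resurrect after dropout
      bad$y[i, ] <- c(1, 0, 1, 0, 0)
      bad$a[i, ] <- bad$y[i, ]
    } else if (mode == 2L) {               # y / a mismatch
      j <- sample(2:5, 1)
      bad$a[i, j] <- 1 - bad$y[i, j]
    } else {                               # non-adherent first interval
      bad$y[i, 1] <- 0
      bad$a[i, 1] <- 0
      bad$y[i, 2:5] <- 0; bad$a[i, 2:5] <- 0
    }
    res <- tryCatch({ validate_cohort(bad); FALSE },
                    scitseq_validation_error = function(e) TRUE)
    rejected <- rejected + res
  }
  expect_equal(rejected, 40L)
})

test_that("write/read round trip is numerically lossless", {
  co <- tiny_cohort(n = 8L, seed = 3L)
  vp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  write_cohort(co, vp, sp)
  co2 <- read_cohort(vp, sp, co$grid)
  expect_equal(co2$x, co$x)
  expect_equal(co2$y, co$y)
  expect_equal(co2$a, co$a)
  expect_equal(unname(co2$s), unname(co$s))
  expect_equal(co2$ids, co$ids)
  unlink(c(vp, sp))
})

test_that("split sizes match the 20% / five-fold protocol", {
  co <- tiny_cohort(n = 205L, seed = 5L)
  co <- split_cohort(co, 0.2, 5L, seed = 10L)
  expect_equal(sum(co$split == 0L), 41L)
  expect_setequal(as.integer(table(co$split[co$split > 0L])),
                  c(33L, 33L, 33L, 33L, 32L))
  co10 <- tiny_cohort(n = 10L, seed = 5L)
  co10 <- split_cohort(co10, 0.2, 2L, seed = 1L)
  expect_equal(sum(co10$split == 0L), 2L)
  expect_equal(sort(as.integer(table(co10$split[co10$split > 0L]))), c(4L, 4L))
})

test_that("splits are seed-deterministic and seed-sensitive", {
  co <- tiny_cohort(n = 60L, seed = 5L)
  a <- split_cohort(co, 0.2, 5L, seed = 3L)$split
  b <- split_cohort(co, 0.2, 5L, seed = 3L)$split
  expect_identical(a, b)
  diffs <- vapply(1:20, function(s) {
    !identical(split_cohort(co, 0.2, 5L, seed = s)$split,
               split_cohort(co, 0.2, 5L, seed = s + 1000L)$split)
  }, logical(1))
  expect_gt(mean(diffs), 0.8)
})

test_that("normalization matches the closed form and round-trips", {
  co <- tiny_cohort(n = 3L, seed = 2L)
  co$x[, , 1] <- matrix(c(2, 4, 6), 3, 6)   # one dimension with known stats
  norm <- suppressWarnings(fit_normalizer(co))
  z <- normalize_mat(norm, co$x[, 1, ], "x")
  expect_equal(z[, 1], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # transformed training data has mean 0 / sd 1 under the population sd
  xmat <- do.call(rbind, lapply(1:6, function(t) co$x[, t, ]))
  zz <- normalize_mat(norm, xmat, "x")
  expect_lt(max(abs(colMeans(zz))), 1e-6)
  expect_lt(max(abs(sqrt(colMeans(sweep(zz, 2, colMeans(zz))^2)) - 1)), 1e-6)
  # round trip
  set.seed(8)
  raw <- matrix(runif(50 * 11, 0, 10), 50, 11)
  back <- denormalize_mat(norm, normalize_mat(norm, raw, "x"), "x")
  expect_equal(back, raw, tolerance = 1e-9)
})

test_that("normalizer statistics never depend on test patients", {
  co <- split_cohort(tiny_cohort(n = 40L, seed = 6L), 0.2, 5L, seed = 2L)
  n1 <- fit_normalizer(co)
  # rewrite all test patients' data arbitrarily
  co2 <- co
  te <- test_idx(co2)
  co2$x[te, , 1:10] <- 9.9
  co2$s[te, ] <- 123
  n2 <- fit_normalizer(co2)
  expect_identical(n1, n2)
  # held-out data is generally off-centre under the training normalizer
  zte <- normalize_mat(n1, co$s[te, , drop = FALSE], "s")
  expect_gt(max(abs(colMeans(zte))), 1e-3)
})

test_that("constant dimensions fall back to sd 1 with a warning", {
  co <- tiny_cohort(n = 5L, seed = 2L)
  co$x[, , 11] <- 2
  expect_warning(norm <- fit_normalizer(co), "constant")
  expect_equal(norm$x_sd[[11]], 1)
})
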