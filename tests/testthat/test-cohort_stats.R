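table2_path <- function() {
  system.file("extdata", "table2.csv", package = "scitseq")
}

test_that("withdrawal rates reproduce the reference table's fractions", {
  wt <- withdrawal_table(table2_path())
  expect_equal(wt$grand_total, 132L)
  expect_equal(unname(wt$period_totals), c(35L, 26L, 14L, 57L))
  rates <- withdrawal_rates(wt)
  expect_equal(unname(rates$year["year1"]), 26.5)
  expect_equal(unname(rates$reason["no clinical improvement"]), 43.9)
  expect_equal(unname(rates$reason["improved efficacy"]), 18.2)
  expect_equal(unname(rates$reason["medical issue"]), 4.5)
  expect_equal(unname(rates$reason["side effects"]), 4.5)
})

test_that("year and reason fractions each total 100% up to rounding", {
  rates <- withdrawal_rates(withdrawal_table(table2_path()))
  expect_lt(abs(sum(rates$year) - 100), 0.2)
  expect_lt(abs(sum(rates$reason) - 100), 0.2)
})

test_that("a uniform toy table gives the hand-computed year fractions", {
  toy <- data.frame(reason = "any", p1 = 1L, p2 = 1L, p3 = 1L, p4 = 1L)
  rates <- withdrawal_rates(withdrawal_table(toy))
  expect_equal(unname(rates$year), c(25.0, 50.0, 25.0))
  empty <- data.frame(reason = "any", p1 = 0L, p2 = 0L, p3 = 0L, p4 = 0L)
  expect_error(withdrawal_rates(withdrawal_table(empty)),
               class = "scitseq_validation_error")
})

test_that("transcribed demographic counts give the printed percentages", {
  tab <- summarize_counts(system.file("extdata", "table1_counts.csv",
                                      package = "scitseq"))
  expect_equal(tab$pct[tab$category == "Male"], 69.8)
  expect_equal(tab$pct[tab$category == "Female"], 30.2)
  expect_equal(tab$pct[tab$variable == "distance_km" &
                         tab$category == "<=10"], 66.3)
  expect_equal(tab$n[tab$category == "Male"], 143)
})

test_that("rounding is half away from zero, not banker's", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.35, 1), 0.4)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(46.75, 1), 46.8)
})

test_that("a single-patient cohort summarises at 100% with zero IQR", {
  co <- tiny_cohort(n = 2L, seed = 51L)
  one <- new_cohort(co$grid, co$ids[1], co$x[1, , , drop = FALSE],
                    co$y[1, , drop = FALSE], co$a[1, , drop = FALSE],
                    co$s[1, , drop = FALSE])
  sm <- summarize_cohort(one)
  filled <- sm$categorical[sm$categorical$n > 0, ]
  expect_true(all(filled$pct == 100.0))
  expect_true(all(sm$continuous$iqr == 0))
  expect_error(summarize_cohort(new_cohort(co$grid, character(0),
                                           co$x[0, , , drop = FALSE],
                                           co$y[0, , drop = FALSE],
                                           co$a[0, , drop = FALSE],
                                           co$s[0, , drop = FALSE])),
               class = "scitseq_validation_error")
})

test_that("median and IQR agree with a sort-based quantile oracle", {
  co <- tiny_cohort(n = 41L, seed = 52L)
  sm <- summarize_cohort(co)
  # type-7 oracle: linear interpolation on the sorted sample
  q7 <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  for (var in sm$continuous$variable) {
    v <- co$s[, var]
    row <- sm$continuous[sm$continuous$variable == var, ]
    expect_equal(row$median, q7(v, 0.5))
    expect_equal(row$iqr, q7(v, 0.75) - q7(v, 0.25))
  }
})

test_that("large-sample summaries are consistent with generator marginals", {
  gt <- generate_cohort(generator_config(n_patients = 100000L, seed = 53L))
  sm <- summarize_cohort(gt$cohort)
  cat_pct <- function(v, c) {
    sm$categorical$pct[sm$categorical$variable == v &
                         sm$categorical$category == c]
  }
  expect_equal(cat_pct("gender", "Male"), 70, tolerance = 0.01)
  expect_equal(cat_pct("distance_km", "<=10"), 66, tolerance = 0.02)
  expect_equal(cat_pct("age", "13-17"), 14.6, tolerance = 0.05)
  expect_equal(sm$continuous$median[sm$continuous$variable == "eos_count"],
               0.37, tolerance = 0.05)
})
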