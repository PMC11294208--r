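#' Round half away from zero
#'
#' Percentages in clinical tables are conventionally rounded half-up;
#' base R's `round()` rounds half to even.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Descriptive summary of a cohort
#'
#' Demographic-table-style output: categorical variables (age group, gender,
#' commute distance, cost/family-income band) as counts with percentages of
#' the whole cohort (one decimal, half-up), split by final adherence status,
#' and continuous laboratory variables as median and interquartile range
#' (type-7 linear-interpolation quantiles), overall and per adherence group.
#' A patient counts as adherent if they completed the final interval.
#'
#' @param cohort A `scit_cohort`.
#' @return A list of two tibbles: `categorical`
#'   (`variable, category, n, pct, adherent, non_adherent`) and
#'   `continuous` (`variable, median, iqr, median_adh, iqr_adh,
#'   median_nonadh, iqr_nonadh`).
#' @export
summarize_cohort <- function(cohort) {
  n <- n_patients(cohort)
  if (n == 0L) abort("empty cohort", class = "scitseq_validation_error")
  s <- cohort$s
  adherent <- cohort$y[, ncol(cohort$y)] == 1
  cats <- list(
    age = cut(s[, "age"], c(-Inf, 12, 17, Inf),
              labels = c("<=12", "13-17", ">=18")),
    gender = factor(ifelse(s[, "gender"] == 1, "Male", "Female"),
                    levels = c("Female", "Male")),
    distance_km = cut(s[, "distance"], c(-Inf, 10, Inf),
                      labels = c("<=10", ">10")),
    cost_income_pct = cut(s[, "cost_income_ratio"], c(-Inf, 30, 50, Inf),
                          labels = c("<30", "30-50", ">50")))
  cat_rows <- lapply(names(cats), function(v) {
    f <- cats[[v]]
    cnt <- as.integer(table(f))
    pcts <- round_half_up(100 * cnt / n, 1L)
    cnt_adh <- as.integer(table(f[adherent]))
    cnt_non <- as.integer(table(f[!adherent]))
    tibble::tibble(variable = v, category = levels(f), n = cnt, pct = pcts,
                   adherent = cnt_adh, non_adherent = cnt_non)
  })
  cont_vars <- setdiff(static_names,
                       c("age", "gender", "distance", "cost_income_ratio",
                         "reserved"))
  med_iqr <- function(v) c(median(v), unname(diff(quantile(v, c(0.25, 0.75)))))
  cont_rows <- lapply(cont_vars, function(v) {
    all_ <- med_iqr(s[, v])
    adh <- if (any(adherent)) med_iqr(s[adherent, v]) else c(NA, NA)
    non <- if (any(!adherent)) med_iqr(s[!adherent, v]) else c(NA, NA)
    tibble::tibble(variable = v, median = all_[1L], iqr = all_[2L],
                   median_adh = adh[1L], iqr_adh = adh[2L],
                   median_nonadh = non[1L], iqr_nonadh = non[2L])
  })
  list(categorical = dplyr::bind_rows(cat_rows),
       continuous = dplyr::bind_rows(cont_rows))
}

#' Percentages from transcribed demographic counts
#'
#' Turns a counts table (columns `variable, category, adherent,
#' non_adherent`) into totals and percentages of the whole cohort, one
#' decimal, half-up — the presentation convention of clinical demographic
#' tables.
#'
#' @param counts A data frame or path to a CSV of counts.
#' @return A tibble with `n = adherent + non_adherent` and `pct`.
#' @export
summarize_counts <- function(counts) {
  if (is.character(counts)) counts <- readr::read_csv(counts,
                                                      show_col_types = FALSE)
  counts <- tibble::as_tibble(counts)
  counts$n <- counts$adherent + counts$non_adherent
  totals <- tapply(counts$n, counts$variable, sum)
  total <- unique(as.vector(totals))
  if (length(total) != 1L) {
    abort("categorical variables disagree on the cohort total",
          class = "scitseq_validation_error")
  }
  counts$pct <- round_half_up(100 * counts$n / total, 1L)
  counts
}

#' Withdrawal reason-by-period contingency table
#'
#' @param counts A data frame (or CSV path) with a `reason` column and one
#'   count column per follow-up period, in chronological order. The bundled
#'   fixture `system.file("extdata", "table2.csv", package = "scitseq")`
#'   carries the reference cohort's table (periods 5--12, 13--18, 19--24
#'   and 25--36 months).
#' @return An object of class `scit_withdrawal_table`: the count matrix with
#'   row, column and grand totals.
#' @export
withdrawal_table <- function(counts) {
  if (is.character(counts)) counts <- readr::read_csv(counts,
                                                      show_col_types = FALSE)
  counts <- as.data.frame(counts)
  m <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(m) <- counts[[1L]]
  if (any(m < 0) || any(m != floor(m))) {
    abort("withdrawal counts must be non-negative integers",
          class = "scitseq_validation_error")
  }
  structure(list(counts = m,
                 reason_totals = rowSums(m),
                 period_totals = colSums(m),
                 grand_total = sum(m)),
            class = "scit_withdrawal_table")
}

#' Per-year and per-reason withdrawal fractions
#'
#' Periods map onto treatment years as year 1 = months 5--12, year 2 =
#' months 13--24 (two periods), year 3 = months 25--36. Fractions are
#' percentages of all non-adherent patients, one decimal, half-up.
#'
#' @param table A `scit_withdrawal_table` with four periods.
#' @return A list: `year` (named percentages for years 1--3), `reason`
#'   (percentage per withdrawal reason) and `grand_total`.
#' @export
withdrawal_rates <- function(table) {
  if (!inherits(table, "scit_withdrawal_table")) {
    table <- withdrawal_table(table)
  }
  if (table$grand_total == 0L) {
    abort("withdrawal table has no events", class = "scitseq_validation_error")
  }
  pt <- table$period_totals
  if (length(pt) != 4L) {
    abort("expected four follow-up periods (5-12, 13-18, 19-24, 25-36 months)",
          class = "scitseq_validation_error")
  }
  years <- c(year1 = unname(pt[1L]), year2 = unname(pt[2L] + pt[3L]),
             year3 = unname(pt[4L]))
  list(year = round_half_up(100 * years / table$grand_total, 1L),
       reason = round_half_up(100 * table$reason_totals / table$grand_total, 1L),
       grand_total = table$grand_total)
}
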