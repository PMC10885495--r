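panel_cards <- function(seed = 21, n = 15, years = 3, drift = 0.25) {
  panel <- generate_cohort(cohort_config(seed = seed, n_facilities = n,
                                         years = years,
                                         quarters_per_year = 1,
                                         drift = drift))
  score_panel(panel)
}

test_that("yearly_summary computes exact mean and n-1 sd per cell", {
  cards <- panel_cards(seed = 31, n = 2, years = 1)
  # override totals by picking two facilities and checking the total row
  tab <- yearly_summary(cards)$table
  tot <- tab[tab$kind == "total", ]
  v <- vapply(cards, `[[`, numeric(1), "total")
  expect_equal(tot$mean, mean(v))
  expect_equal(tot$sd, stats::sd(v))
  expect_equal(tot$n, 2L)

  # hand arithmetic: panel of two with totals 50 and 60
  expect_equal(stats::sd(c(50, 60)), 7.0710678, tolerance = 1e-6)

  # identical scores across the panel give sd 0.00 cells
  one <- cards[[1]]
  two <- cards[[1]]
  two$facility_id <- "F99"
  tt <- yearly_summary(list(one, two))$table
  expect_true(all(tt$sd == 0))
  expect_true(all(grepl("± 0.00", tt$display[tt$kind == "total"])))
})

test_that("yearly_summary rejects unbalanced panels unless flagged", {
  cards <- panel_cards(seed = 32, n = 3, years = 2)
  drop_one <- cards[-1]  # removes one facility-year
  expect_error(yearly_summary(drop_one), "unbalanced")
  expect_s3_class(yearly_summary(drop_one, unbalanced = TRUE), "pivas_trend")
})

test_that("normality_check wraps Shapiro-Wilk and guards constant input", {
  set.seed(77)
  # heavily skewed sample rejects normality
  skewed <- rexp(15)^3
  expect_lt(normality_check(skewed)$p, 0.05)
  # calibration: standard-normal samples rarely reject (scaled-down MC)
  rejections <- vapply(1:200, function(i)
    normality_check(rnorm(15))$p < 0.05, logical(1))
  expect_lt(mean(rejections), 0.10)
  cst <- normality_check(rep(4, 15))
  expect_equal(cst$flag, "constant")
  expect_true(is.na(cst$p))
  expect_error(normality_check(c(1, 2)), "at least 3")
})

test_that("pairwise_compare: identity, exact enumeration, determinism", {
  x <- c(50, 60, 45, 70, 55, 52, 61, 58, 49, 63, 66, 48, 57, 59, 54)
  id <- pairwise_compare(x, x)
  expect_equal(id$effect, 0)
  expect_equal(id$p, 1)
  expect_true(id$zero_variance)

  # all 15 differences equal +5: only the two constant-sign patterns are
  # as extreme, so the exact two-sided p is 2/2^15
  shift <- pairwise_compare(x, x + 5)
  expect_equal(shift$p, 2 / 2^15)
  expect_equal(shift$effect, 5)
  expect_equal(shift$se, 0)
  expect_match(shift$method, "exact")

  # exact result agrees with itself and with a seeded Monte-Carlo run
  set.seed(123)
  y <- x + rnorm(15, 1, 4)
  e1 <- pairwise_compare(x, y)
  e2 <- pairwise_compare(x, y)
  expect_identical(e1, e2)
  mc1 <- pairwise_compare(x, y, exact_limit = 1, n_permutations = 4000,
                          seed = 99)
  mc2 <- pairwise_compare(x, y, exact_limit = 1, n_permutations = 4000,
                          seed = 99)
  expect_identical(mc1$p, mc2$p)
  expect_match(mc1$method, "monte-carlo")
  expect_equal(mc1$p, e1$p, tolerance = 0.05)
})

test_that("exact p-value matches a brute-force enumeration oracle at small n", {
  d <- c(2, -1, 3, 0.5, -2, 4, 1)
  n <- length(d)
  # oracle: enumerate sign patterns via expand.grid
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_means <- grid %*% d / n
  p_oracle <- mean(abs(null_means) >= abs(mean(d)) - 1e-12)
  got <- pairwise_compare(rep(0, n), d)
  expect_equal(got$p, p_oracle)
})

test_that("trend_comparisons covers every measure and year pair", {
  cards <- panel_cards(seed = 33, n = 8, years = 3)
  cmp <- trend_comparisons(cards, seed = 1)
  expect_equal(nrow(cmp), (20 + 5 + 1) * 3)  # 3 year pairs each
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$zero_variance == (cmp$se == 0 & cmp$effect == 0)))
  # an improving cohort should improve its total in every pair
  tot <- cmp[cmp$measure == "total", ]
  expect_true(all(tot$effect > 0))
  holm <- trend_comparisons(cards, seed = 1, adjust = "holm")
  expect_true(all(holm$p >= cmp$p - 1e-12))
})
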