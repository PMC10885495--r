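test_that("cohort_config validates its stated world", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, drift = 1.2), "drift")
  expect_error(cohort_config(seed = 1, drift = -0.1), "drift")
  cfg <- cohort_config(seed = 1)
  expect_equal(cfg$n_facilities, 15)
  expect_equal(cfg$years, 3)
  expect_equal(cfg$quarters_per_year, 4)
})

test_that("generator contract: 45 facility-years, all audit-pass, truth aligned", {
  panel <- generate_cohort(cohort_config(seed = 42))
  expect_equal(length(panel$submissions), 15 * 3 * 4)
  expect_equal(nrow(panel$truth), 45)
  status <- vapply(panel$submissions, function(s)
    audit_submission(s)$status, character(1))
  expect_true(all(status == "pass"))
  # truth rows align one-to-one with facility-year groups
  key <- unique(vapply(panel$submissions, function(s)
    paste(s$facility_id, s$year), character(1)))
  expect_setequal(key, paste(panel$truth$facility_id, panel$truth$year))
})

test_that("same config generates byte-identical panels", {
  p1 <- generate_cohort(cohort_config(seed = 7))
  p2 <- generate_cohort(cohort_config(seed = 7))
  expect_identical(p1$submissions, p2$submissions)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_cohort(cohort_config(seed = 8))
  expect_false(identical(p1$truth, p3$truth))
})

test_that("latent quality 1 back-solves to the best branch everywhere", {
  panel <- generate_cohort(cohort_config(seed = 5, n_facilities = 3,
                                         baseline_mean = 1, baseline_sd = 0,
                                         noise = 0))
  for (cd in score_panel(panel)) expect_equal(cd$total, 100)
})

test_that("noiseless generation inverts exactly: branch agreement 100%, rho 1", {
  panel <- generate_cohort(cohort_config(seed = 9, noise = 0))
  rec <- recover_quality(panel)
  expect_equal(rec$branch_agreement, 1)
  expect_equal(rec$scores$truth_total, rec$scores$scored_total)
  # quality ordering is recovered up to rubric quantization (the score is
  # a step function of quality, so saturating years show ties)
  expect_gt(rec$spearman, 0.95)
  expect_true(all(rec$spearman_by_year > 0.85))
})

test_that("moderate noise keeps recovery strong; shuffled truth kills it", {
  panel <- generate_cohort(cohort_config(seed = 13))
  rec <- recover_quality(panel)
  expect_gte(rec$spearman, 0.8)
  expect_equal(rec$branch_agreement, 1)  # noise moves targets, not items
  # negative control: break the truth alignment
  shuffled <- panel
  set.seed(1)
  shuffled$truth$quality <- sample(panel$truth$quality)
  rho <- suppressWarnings(
    cor(shuffled$truth$quality, rec$scores$scored_total, method = "spearman"))
  expect_lt(abs(rho), 0.35)
})

test_that("positive drift raises yearly means and shrinks dispersion", {
  panel <- generate_cohort(cohort_config(seed = 17))
  rec <- recover_quality(panel)
  by_year <- split(rec$scores$scored_total, rec$scores$year)
  means <- vapply(by_year, mean, numeric(1))
  sds <- vapply(by_year, sd, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(diff(sds) < 0))
  # null world: no drift leaves expected totals flat (same facilities)
  null <- generate_cohort(cohort_config(seed = 17, drift = 0, noise = 0))
  nrec <- recover_quality(null)
  nm <- vapply(split(nrec$scores$scored_total, nrec$scores$year),
               mean, numeric(1))
  expect_equal(unname(diff(nm)), c(0, 0))
})

test_that("generated panels round-trip through the submission file format", {
  panel <- generate_cohort(cohort_config(seed = 23, n_facilities = 2,
                                         years = 1, quarters_per_year = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_submissions(panel$submissions, path)
  back <- read_submissions(path)
  expect_equal(length(back), length(panel$submissions))
  for (i in seq_along(back)) {
    a <- panel$submissions[[i]]$items
    b <- back[[i]]$items
    expect_equal(b[names(a)], lapply(a, function(v)
      if (is.integer(v)) as.numeric(v) else v),
      tolerance = 1e-12)
  }
})
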