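rub <- default_rubric()
refs <- regional_reference()

score_one <- function(id, sub) {
  score_indicator(derive_metrics(sub), sub, rub$indicators[[id]], refs)
}

test_that("derived metrics follow the data-source formulas", {
  m <- derive_metrics(parse_submission(c(D05 = "600", D15 = "200")))
  expect_equal(m$m_daily, 800)

  m <- derive_metrics(parse_submission(
    c(C02 = "2", C07 = "3", C03 = "4", C08 = "1")))
  expect_equal(m$training_ratio, (2 + 3) / (4 + 1))  # = 1

  m <- derive_metrics(full_submission())
  expect_equal(m$consoles, 5)
  expect_equal(m$pharmacist_prop, 1)
  expect_equal(m$bed_infusion, 750 / 180)
  expect_equal(m$groups_per_syringe, 70000 / 30000)
  expect_equal(m$temp_rate, 200 / 600)
  expect_equal(m$disposition_rate, 270 / 300)
  expect_equal(m$error_rate, (50 + 40 + 30) / 70000)
  expect_equal(m$equipment_count, 5)
  expect_equal(m$traceable_count, 5)
  expect_equal(m$disinfection_methods, 2)
})

test_that("zero denominators give undefined markers, never silent zeros", {
  m <- derive_metrics(sub_with(D06 = "0", D17 = "0"))
  expect_true(is.na(m$disposition_rate))
  expect_true("disposition_rate" %in% attr(m, "undefined"))
  m <- derive_metrics(parse_submission(c(D15 = "10")))
  expect_true(is.na(m$m_daily))  # missing D05
})

test_that("rubric maxima match the printed matrix", {
  mx <- rubric_maxima(rub)
  expect_equal(length(mx$indicator), 20)
  expect_equal(unname(mx$indicator),
               c(5, 1, 5, 5, 5, 4, 10, 5, 3, 5, 5, 5, 6, 5, 5, 5, 5, 3, 8, 5))
  expect_equal(mx$category,
               c(hardware = 11, personnel = 14, work_efficiency = 49,
                 infection_control = 13, information = 13))
  expect_equal(mx$total, 100)
  # per-indicator branch awards never exceed the indicator maximum
  for (spec in rub$indicators) expect_true(max(spec$levels) <= spec$max)
})

test_that("worked scoring examples from the matrix text", {
  # 800 bags/day needs >= 300 m2; 350 m2 qualifies
  expect_equal(score_one("H1", full_submission())$points, 5)
  expect_equal(score_one("H1", sub_with(B01 = "250"))$points, 0)
  # area requirement grows by 50 m2 per extra 500 bags above 3000/day
  expect_equal(score_one("H1", sub_with(D05 = "3300", D15 = "200",
                                        B01 = "700"))$points, 5)
  expect_equal(score_one("H1", sub_with(D05 = "3300", D15 = "201",
                                        B01 = "700"))$points, 0)

  # fewer than 500 prescriptions reviewed per person: 6 points
  expect_equal(score_one("W7", sub_with(D04 = "450"))$points, 6)
  expect_equal(score_one("W7", sub_with(D04 = "700"))$points, 3)
  expect_equal(score_one("W7", sub_with(D04 = "900"))$points, 0)

  # temporary order deployment rate above 5%: 5 points
  expect_equal(score_one("W6", sub_with(D05 = "1000", D15 = "60"))$points, 5)
  expect_equal(score_one("W6", sub_with(D05 = "1000", D15 = "40"))$points, 3)
  expect_equal(score_one("W6", sub_with(D05 = "1000", D15 = "20"))$points, 0)

  # training ratio exactly 1 sits in the 0.2-1 band: 2 points
  expect_equal(score_one("P1", full_submission())$points, 2)
  expect_equal(score_one("P1", sub_with(C02 = "8", C07 = "7"))$points, 5)

  # a single disinfection method scores 0
  expect_equal(score_one("I3", sub_with(E11 = "ethanol"))$points, 0)
  expect_equal(score_one("I3", full_submission())$points, 3)

  # director threshold: supervising pharmacist + bachelor
  expect_equal(score_one("P3", full_submission())$points, 4)
  expect_equal(score_one("P3", sub_with(C09 = "pharmacist"))$points, 2)
  expect_equal(score_one("P3", sub_with(C05 = "associate"))$points, 2)
})

test_that("scorecards conserve points and are deterministic", {
  sub <- full_submission()
  cd1 <- score_submission(sub, rub, refs)
  cd2 <- score_submission(sub, rub, refs)
  expect_identical(cd1, cd2)
  expect_equal(cd1$total, sum(cd1$indicators$points))
  expect_equal(cd1$total, sum(cd1$category_scores))
  expect_true(all(cd1$indicators$points <= cd1$indicators$max))
  # the fixture's hand-computed card
  expect_equal(unname(cd1$category_scores),
               c(11, 2 + 5 + 4, 10 + 3 + 3 + 5 + 5 + 5 + 6 + 5 + 5,
                 5 + 5 + 3, 8 + 2))
})

test_that("a back-solved maximal submission scores 100 and a minimal one the branch-floor sum", {
  best <- generate_cohort(cohort_config(seed = 11, n_facilities = 2, years = 1,
                                        quarters_per_year = 1,
                                        baseline_mean = 1, baseline_sd = 0,
                                        noise = 0, drift = 0))
  for (cd in score_panel(best)) expect_equal(cd$total, 100)

  worst <- generate_cohort(cohort_config(seed = 11, n_facilities = 2, years = 1,
                                         quarters_per_year = 1,
                                         baseline_mean = 0, baseline_sd = 0,
                                         noise = 0, drift = 0))
  floor_total <- sum(vapply(rub$indicators, function(s) min(s$levels),
                            numeric(1)))
  for (cd in score_panel(worst)) expect_equal(cd$total, floor_total)
})

test_that("undefined-input policy: lenient scores 0 with annotation, strict errors", {
  rec <- full_record()
  sub <- parse_submission(rec[names(rec) != "D04"])
  cd <- score_submission(sub, rub, refs)
  expect_equal(cd$indicators["W7", "points"], 0)
  expect_equal(cd$indicators["W7", "branch"], "undefined")
  expect_true(any(grepl("W7", cd$annotations)))
  expect_error(score_submission(sub, rub, refs, policy = "strict"),
               "W7.*D04")
})

test_that("monotonicity: better inputs never lower the score", {
  base <- full_submission()
  for (d04 in c(100, 499, 500, 800, 801, 2000)) {
    lower <- score_one("W7", sub_with(D04 = as.character(d04)))$points
    higher <- score_one("W7", sub_with(D04 = as.character(d04 + 50)))$points
    expect_lte(higher, lower)
  }
  # raising the training ratio never lowers staff-training points
  prev <- -1
  for (s in c(1, 2, 5, 10, 11, 20)) {
    pts <- score_one("P1", sub_with(C02 = as.character(s), C07 = "0",
                                    C03 = "6", C08 = "4"))$points
    expect_gte(pts, prev)
    prev <- pts
  }
  # adding a dispensed drug class never lowers the infusion-type score
  s0 <- score_one("W1", sub_with(D12 = "0"))$points
  s1 <- score_one("W1", full_submission())$points
  expect_gte(s1, s0)
})

test_that("branch tables are exhaustive over randomized inputs", {
  set.seed(404)
  for (i in 1:200) {
    sub <- sub_with(
      B01 = as.character(round(runif(1, 0, 1500))),
      B09 = as.character(sample(0:100, 1)),
      B10 = as.character(sample(1:1200, 1)),
      B02 = "2000",
      D05 = as.character(sample(1:4000, 1)),
      D15 = as.character(sample(0:500, 1)),
      D04 = as.character(sample(0:1500, 1)),
      D13 = as.character(sample(0:300, 1)),
      D06 = as.character(sample(1:500, 1)),
      D17 = "0", D16 = "1.2",
      E01 = as.character(sample(0:20, 1)))
    cd <- score_submission(sub, rub, refs)
    expect_false(any(is.na(cd$indicators$points)))
    expect_true(all(cd$indicators$points >= 0 &
                    cd$indicators$points <= cd$indicators$max))
  }
})

test_that("free-text parsing: unknown tokens counted with a warning note", {
  m <- derive_metrics(sub_with(E11 = "ethanol、mystery fluid"))
  expect_equal(m$disinfection_methods, 2)  # 1 known + 1 unknown block
  expect_true(any(grepl("E11 unknown", attr(m, "notes"))))
  m <- derive_metrics(sub_with(F01 = "dispensing scanner; hoverboard"))
  expect_equal(m$equipment_count, 2)
  expect_equal(m$traceable_count, 1)
})

test_that("cohort-derived reference fallback averages the cohort metrics", {
  subs <- list(full_submission(), sub_with(D05 = "1000", D15 = "100"))
  cr <- cohort_reference(subs)
  expect_equal(cr$provenance, "cohort-derived")
  expect_equal(cr$avg_daily_deployment, mean(c(800, 1100)))
  expect_error(regional_reference(avg_error_rate = 0), "positive")
})
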