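test_that("schema enumerates exactly 67 items partitioned 12/12/10/19/11/3", {
  sch <- pivas_schema()
  expect_equal(nrow(sch), 67)
  expect_equal(anyDuplicated(sch$item), 0)
  expect_equal(unname(table(sch$aspect)[c("A", "B", "C", "D", "E", "F")]),
               table(factor(c(rep("A", 12), rep("B", 12), rep("C", 10),
                              rep("D", 19), rep("E", 11), rep("F", 3)))),
               ignore_attr = TRUE)
  # only the pure contact/basic-info items are optional
  expect_setequal(sch$item[!sch$required],
                  c("A03", "A04", "A05", "A06", "A07", "A10", "A11"))
})

test_that("parse_submission coerces by declared type and rejects bad values", {
  sub <- parse_submission(c(B01 = "350", D05 = "600", D15 = "200"))
  expect_identical(sub$items$B01, 350)
  expect_identical(sub$items$D05, 600)
  expect_error(parse_submission(c(B01 = "large")), "B01 expects float")
  expect_error(parse_submission(c(D05 = "12.7")), "D05 expects integer")
  expect_error(parse_submission(list(B01 = "1", B01 = "2")), "duplicate")
  expect_error(parse_submission(c(ZZ9 = "1"), unknown = "error"), "unknown")
  expect_warning(parse_submission(c(ZZ9 = "1", B01 = "10")), "unknown")
  expect_error(parse_submission(c(B01 = "1"), quarter = 7), "quarter")
})

test_that("a complete valid record yields a 67-item submission", {
  sub <- full_submission()
  expect_s3_class(sub, "pivas_submission")
  expect_equal(length(sub$items), 67)
  expect_true(is.logical(sub$items$F02))
})

test_that("parse_submission o as_record is the identity on valid submissions", {
  sub <- full_submission()
  rt <- parse_submission(as_record(sub), facility_id = sub$facility_id,
                         year = sub$year, quarter = sub$quarter)
  expect_equal(rt$items, sub$items)
  # and via the delimited-file round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_submissions(list(sub), path)
  back <- read_submissions(path)
  expect_equal(back[[1]]$items[order(names(back[[1]]$items))],
               sub$items[order(names(sub$items))])
})

test_that("audit passes a consistent record with zero findings", {
  rep <- audit_submission(full_submission())
  expect_equal(rep$status, "pass")
  expect_equal(nrow(rep$findings), 0)
})

test_that("audit flags containment, ordering, range and rate inconsistencies", {
  # unreasonable prescriptions exceed total prescriptions
  rep <- audit_submission(sub_with(D06 = "50000", D17 = "100"))
  expect_equal(rep$status, "fail")
  expect_true(any(rep$findings$item_id == "D06" &
                  rep$findings$severity == "error"))

  # beds served exceed the hospital's beds (B02 > B10 ordering)
  rep <- audit_submission(sub_with(B02 = "500", B10 = "600", D10 = "3000"))
  expect_true(any(rep$findings$item_id == "B10" &
                  grepl("B02", rep$findings$message)))

  # percentage out of range
  rep <- audit_submission(sub_with(E02 = "104"))
  expect_true(any(rep$findings$item_id == "E02" &
                  rep$findings$rule_id == "range"))

  # D16 disagreeing with 100*D06/D14 beyond half a point -> warning only
  rep <- audit_submission(sub_with(D16 = "2.5"))
  expect_equal(rep$status, "pass")
  expect_true(any(rep$findings$item_id == "D16" &
                  rep$findings$severity == "warning"))

  # missing required quantitative item
  rec <- full_record()
  sub <- parse_submission(rec[names(rec) != "D04"])
  rep <- audit_submission(sub)
  expect_equal(rep$status, "fail")
  expect_true(any(rep$findings$item_id == "D04" &
                  rep$findings$rule_id == "completeness"))
})

test_that("audit is idempotent and order-independent over rules", {
  sub <- sub_with(D06 = "50000", E02 = "104")
  rules <- default_audit_rules()
  r1 <- audit_submission(sub, rules)
  r2 <- audit_submission(sub, rules)
  r3 <- audit_submission(sub, rev(rules))
  expect_identical(r1$findings, r2$findings)
  expect_identical(r1$findings, r3$findings)
})

test_that("yearly aggregation sums counts, averages rates, rescales D16", {
  qs <- lapply(1:4, function(q)
    parse_submission(full_record(), facility_id = "T01", year = 2020,
                     quarter = q))
  yr <- aggregate_year(qs)
  expect_true(is.na(yr$quarter))
  expect_equal(yr$n_quarters, 4L)
  expect_equal(yr$items$D01, 4 * 70000)   # period count: summed
  expect_equal(yr$items$D05, 600)         # daily average: averaged
  expect_equal(yr$items$E01, 52)          # cleaning count: summed
  expect_equal(yr$items$D16, 100 * (4 * 300) / (4 * 38500))
  expect_error(aggregate_year(list(qs[[1]],
    parse_submission(full_record(), facility_id = "X", year = 2020))),
    "one facility-year")
})
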