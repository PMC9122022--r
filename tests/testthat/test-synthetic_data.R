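test_that("generator is seed-deterministic and empty-safe", {
  expect_identical(nrow(generate_cohort(generator_params(0))$patients), 0L)
  a <- generate_cohort(generator_params(30, seed = 8))
  b <- generate_cohort(generator_params(30, seed = 8))
  expect_identical(a, b)
  c_ <- generate_cohort(generator_params(30, seed = 9))
  expect_false(identical(a$events, c_$events))
})

test_that("generated cohorts satisfy the container and eligibility invariants", {
  co <- generate_cohort(generator_params(150, seed = 21))
  expect_s3_class(validate_cohort(co), "oa_cohort")
  cs <- default_codesets()
  for (i in seq_len(nrow(co$patients))) {
    id <- co$patients$patient_id[i]
    idx <- index_date(co$events[co$events$patient_id == id, ], cs)
    expect_false(is.na(idx))
    expect_true(is_eligible(co$patients[i, ], idx))
  }
  # no exclusions fire when injection is off
  excl <- apply_exclusions(co, cs)
  expect_identical(sum(excl$outcomes$excluded), 0L)
})

test_that("generator recovers the stated marginals at n = 2000", {
  co <- generate_cohort(generator_params(2000, seed = 11))
  lat <- attr(co, "latent")
  expect_lt(abs(100 * mean(lat$gold_case) - 67), 2)
  gold <- adjudicate_cohort(co)
  s <- summarize_cohort(co, gold)
  expect_lt(abs(s$pct_imaging - 73), 3)

  co3 <- generate_cohort(generator_params(2000, seed = 3))
  s3 <- summarize_cohort(co3, adjudicate_cohort(co3))
  expect_lt(abs(s3$mean_age - 63.8), 0.5)
  expect_lt(abs(s3$pct_women - 53), 3)
  expect_lt(abs(s3$pct_oa_code - 60), 3)
  expect_lt(abs(s3$pct_pain_code - 78), 3)
})

test_that("exclusion injection produces excludable patients", {
  p <- generator_params(200, seed = 17,
                        exclusion_rates = c(ra = 0.05, gout = 0.05,
                                            pseudogout = 0, psa = 0,
                                            tkr = 0.05))
  co <- generate_cohort(p)
  excl <- apply_exclusions(co)
  expect_gt(sum(excl$outcomes$excluded), 0L)
  expect_true(all(excl$outcomes$reason[excl$outcomes$excluded] %in%
                    c("ra", "gout", "tkr_before_index")))
})

test_that("row fixtures reject infeasible count specifications", {
  expect_error(build_row_fixture("one_oa_code", 85, 57, 39, 40),
               "infeasible")
  expect_error(build_row_fixture("one_oa_code", 85, 57, 90, 10),
               "infeasible")
  expect_error(build_row_fixture("nonsense", 85, 57, 39, 25), "unknown")
})

test_that("a row fixture reproduces its counts through the full pipeline", {
  fx <- build_row_fixture("oa2_6mo", 85, 57, 12, 11)
  gold <- adjudicate_cohort(fx$cohort)
  expect_identical(sum(gold$status == "oa_positive"), 57L)
  dec <- evaluate_all(fx$cohort, list(fx$algorithm))
  expect_identical(sum(dec[, "oa2_6mo"]), 12L)
  t <- contingency(stats::setNames(dec[, 1], rownames(dec)), gold)
  expect_identical(unclass(t), unclass(fx$expected))
})

test_that("exclusion fixture reproduces the published attrition", {
  fx <- build_exclusion_fixture()
  expect_identical(nrow(fx$patients), 93L)
  excl <- apply_exclusions(fx)
  expect_identical(nrow(excl$cohort$patients), 85L)
  reasons <- excl$outcomes$reason[excl$outcomes$excluded]
  expect_identical(sum(reasons == "gout"), 4L)
  expect_identical(sum(reasons == "ra"), 2L)
  expect_identical(sum(reasons == "tkr_before_index"), 1L)
  expect_identical(sum(reasons == "insufficient_data"), 1L)

  # with injection disabled all 93 are retained
  clean <- build_exclusion_fixture(inject = FALSE)
  expect_identical(sum(apply_exclusions(clean)$outcomes$excluded), 0L)
})
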