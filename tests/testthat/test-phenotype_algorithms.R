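cs <- default_codesets()

test_that("index date is the first OA/pain code inside the assessment period", {
  ev <- data.frame(patient_id = "P1",
                   code = c(cs$knee_oa[1], cs$knee_pain[1]),
                   event_date = as.Date(c("1999-06-01", "2003-02-10")))
  expect_identical(index_date(ev, cs), as.Date("2003-02-10"))

  none <- data.frame(patient_id = "P1", code = "ZZZZZ",
                     event_date = as.Date("2003-02-10"))
  expect_true(is.na(index_date(none, cs)))

  tie <- data.frame(patient_id = "P1",
                    code = c(cs$knee_pain[1], cs$knee_oa[1]),
                    event_date = as.Date(c("2001-01-05", "2001-01-05")))
  expect_identical(index_date(tie, cs), as.Date("2001-01-05"))
})

test_that("eligibility enforces age 40-90 and a year of registration", {
  pat <- function(by, rs, re) {
    data.frame(patient_id = "P1", sex = "male", birth_year = by,
               registration_start = as.Date(rs),
               registration_end = as.Date(re))
  }
  ok <- is_eligible(pat(1960L, "2000-01-01", "2010-01-01"),
                    as.Date("2005-01-01"))
  expect_true(ok)
  young <- is_eligible(pat(1980L, "2000-01-01", "2010-01-01"),
                       as.Date("2005-01-01"))
  expect_false(young)
  expect_identical(attr(young, "reasons"), "age")
  short <- is_eligible(pat(1960L, "2004-10-01", "2010-01-01"),
                       as.Date("2005-01-01"))
  expect_false(short)
  expect_identical(attr(short, "reasons"), "registration")
})

test_that("pair rule boundaries are inclusive and match the brute-force oracle", {
  base <- as.Date("2005-01-01")
  expect_true(meets_pair_rule(base + c(0, 7), 7, 183))
  expect_false(meets_pair_rule(base + c(0, 5), 7, 183))
  expect_true(meets_pair_rule(base + c(0, 183), 7, 183))
  expect_false(meets_pair_rule(base + c(0, 184), 7, 183))
  expect_false(meets_pair_rule(base, 7, 183))

  set.seed(7)
  for (i in 1:50) {
    n <- sample(0:12, 1)
    d <- sort(base + sample(0:500, n, replace = TRUE))
    sep <- sample(c(0, 7, 30), 1)
    win <- sample(c(90, 183, 365, Inf), 1)
    expect_identical(meets_pair_rule(d, sep, win), oracle_pair(d, sep, win),
                     info = sprintf("case %d: sep=%s win=%s", i, sep, win))
  }
})

test_that("algorithm decisions follow the declarative definitions", {
  algs <- default_algorithms(imaging_variants = TRUE)
  one_oa <- record_from_offsets(oa = 0)
  expect_true(apply_algorithm(one_oa, algs$one_oa_code, cs))
  expect_false(apply_algorithm(one_oa, algs$one_pain_code, cs))

  two_oa_close <- record_from_offsets(oa = c(0, 10))
  expect_true(apply_algorithm(two_oa_close, algs$oa2_6mo, cs))
  expect_false(apply_algorithm(two_oa_close, algs$one_oa_code, cs))

  two_oa_far <- record_from_offsets(oa = c(0, 400))
  expect_false(apply_algorithm(two_oa_far, algs$oa2_6mo, cs))
  expect_false(apply_algorithm(two_oa_far, algs$oa2_12mo, cs))

  # same-day OA+pain pair fails the 7-day mixed-rule separation by default
  same_day <- record_from_offsets(oa = 0, pain = 0)
  expect_false(apply_algorithm(same_day, algs$oa_pain_6mo, cs))
  relaxed <- default_algorithms(mixed_rule_separation_days = 0)
  expect_true(apply_algorithm(same_day, relaxed$oa_pain_6mo, cs))

  # imaging variants require imaging within two years of a qualifying code
  no_img <- record_from_offsets(oa = c(0, 10))
  expect_false(apply_algorithm(no_img, algs$oa2_6mo_img, cs))
  with_img <- record_from_offsets(oa = c(0, 10), img = 700)
  expect_true(apply_algorithm(with_img, algs$oa2_6mo_img, cs))
  far_img <- record_from_offsets(oa = c(0, 10), img = 1000)
  expect_false(apply_algorithm(far_img, algs$oa2_6mo_img, cs))
  # a coded report also counts as imaging evidence
  rep_img <- apply_algorithm(no_img, algs$oa2_6mo_img, cs,
                             imaging = make_report(date = as.Date("2005-01-01")))
  expect_true(rep_img)
})

test_that("engine agrees with exhaustive enumeration on random records", {
  algs <- default_algorithms(imaging_variants = TRUE)
  set.seed(42)
  for (i in 1:200) {
    oa <- sample(0:900, sample(0:6, 1), replace = TRUE)
    pain <- sample(0:900, sample(0:6, 1), replace = TRUE)
    img <- sample(0:900, sample(0:2, 1), replace = TRUE)
    ev <- record_from_offsets(oa = oa, pain = pain, img = img)
    for (alg in algs) {
      expect_identical(
        apply_algorithm(ev, alg, cs),
        oracle_algorithm(alg, sort(oa), sort(pain), img),
        info = sprintf("record %d, algorithm %s", i, alg$name))
    }
  }
})

test_that("six-month positives are a subset of twelve-month positives", {
  co <- generate_cohort(generator_params(400, seed = 19))
  dec <- evaluate_all(co, default_algorithms(), cs)
  expect_true(all(dec[, "oa2_12mo"] >= dec[, "oa2_6mo"]))
  expect_true(all(dec[, "pain2_12mo"] >= dec[, "pain2_6mo"]))
  expect_true(all(dec[, "oa_pain_12mo"] >= dec[, "oa_pain_6mo"]))
  # and at least one record where the window genuinely matters
  expect_gt(sum(dec[, "oa2_12mo"]), sum(dec[, "oa2_6mo"]))
})

test_that("evaluate_all is deterministic and empty-safe", {
  co <- generate_cohort(generator_params(50, seed = 23))
  expect_identical(evaluate_all(co, default_algorithms(), cs),
                   evaluate_all(co, default_algorithms(), cs))
  m <- evaluate_all(new_cohort(), default_algorithms(), cs)
  expect_identical(dim(m), c(0L, 8L))
})

test_that("exclusion rules match the stated semantics", {
  base <- as.Date("2005-03-01")
  mk <- function(extra = NULL) {
    ev <- data.frame(patient_id = "P1", code = cs$knee_pain[1],
                     event_date = base)
    if (!is.null(extra)) ev <- rbind(ev, extra)
    tiny_cohort(events = ev,
                imaging = make_report(date = base))
  }
  # one gout code only: retained
  one_gout <- mk(data.frame(patient_id = "P1",
                            code = cs$exclusion_gout[1],
                            event_date = base + 30))
  expect_false(apply_exclusions(one_gout, cs)$outcomes$excluded)
  # two gout codes 6 days apart: retained (needs >= 7)
  close_gout <- mk(data.frame(patient_id = "P1",
                              code = cs$exclusion_gout[1],
                              event_date = base + c(30, 36)))
  expect_false(apply_exclusions(close_gout, cs)$outcomes$excluded)
  # two gout codes 7 days apart: excluded, reason gout
  two_gout <- mk(data.frame(patient_id = "P1",
                            code = cs$exclusion_gout[1],
                            event_date = base + c(30, 37)))
  out <- apply_exclusions(two_gout, cs)$outcomes
  expect_true(out$excluded)
  expect_identical(out$reason, "gout")
  # TKR after index: retained; before index: excluded
  tkr_after <- mk(data.frame(patient_id = "P1", code = cs$tkr[1],
                             event_date = base + 100))
  expect_false(apply_exclusions(tkr_after, cs)$outcomes$excluded)
  tkr_before <- mk(data.frame(patient_id = "P1", code = cs$tkr[1],
                              event_date = base - 100))
  out2 <- apply_exclusions(tkr_before, cs)$outcomes
  expect_identical(out2$reason, "tkr_before_index")
  # RA outranks gout in the exclusion log
  both <- mk(data.frame(patient_id = "P1",
                        code = c(cs$exclusion_gout[1], cs$exclusion_gout[1],
                                 cs$exclusion_ra[1], cs$exclusion_ra[1]),
                        event_date = base + c(10, 20, 30, 40)))
  expect_identical(apply_exclusions(both, cs)$outcomes$reason, "ra")
})

test_that("retained set does not depend on patient processing order", {
  co <- build_exclusion_fixture()
  shuffled <- new_cohort(co$patients[rev(seq_len(nrow(co$patients))), ],
                         co$events, co$imaging, co$questionnaire)
  a <- apply_exclusions(co, cs)
  b <- apply_exclusions(shuffled, cs)
  expect_setequal(a$cohort$patients$patient_id, b$cohort$patients$patient_id)
})

test_that("algorithm definitions round-trip through YAML", {
  algs <- default_algorithms(imaging_variants = TRUE)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_algorithms(algs, p)
  expect_equal(read_algorithms(p), algs)
})
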