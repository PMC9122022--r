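tt <- function(tp, fp, fn, tn) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "oa_twobytwo")
}

test_that("PPV and sensitivity reproduce the published point estimates", {
  expect_identical(ppv(tt(25, 14, 32, 14)), 64.1)
  expect_identical(ppv(tt(11, 1, 46, 27)), 91.7)
  expect_identical(ppv(tt(5, 0, 0, 0)), 100.0)
  expect_identical(sensitivity(tt(25, 14, 32, 14)), 43.9)
  expect_identical(sensitivity(tt(11, 1, 46, 27)), 19.3)
  expect_identical(sensitivity(tt(0, 3, 5, 2)), 0.0)
  # undefined denominators are missing, never 0 or 100
  expect_true(is.na(ppv(tt(0, 0, 3, 2))))
  expect_true(is.na(sensitivity(tt(0, 3, 0, 2))))
})

test_that("Wald intervals reproduce the published CIs, with clipping", {
  expect_identical(wald_ci(25, 39), c(49.0, 79.2))
  expect_identical(wald_ci(11, 12), c(76.0, 100.0))
  expect_identical(wald_ci(12, 12), c(100.0, 100.0))
  expect_identical(wald_ci(0, 12), c(0.0, 0.0))
  expect_identical(wald_ci(0, 0), c(NA_real_, NA_real_))
})

test_that("every printed interval in both tables recomputes from (k, n)", {
  for (ref in list(table2_reference(), table3_reference())) {
    n_gold <- attr(ref, "n_gold_positive")
    for (i in seq_len(nrow(ref))) {
      expect_identical(wald_ci(ref$n_tp[i], ref$n_satisfying[i]),
                       c(ref$ppv_lo[i], ref$ppv_hi[i]),
                       info = paste("ppv ci", ref$algorithm[i]))
      expect_identical(wald_ci(ref$n_tp[i], n_gold),
                       c(ref$sens_lo[i], ref$sens_hi[i]),
                       info = paste("sens ci", ref$algorithm[i]))
      expect_identical(round_half_up(100 * ref$n_tp[i] / ref$n_satisfying[i]),
                       ref$ppv[i])
      expect_identical(round_half_up(100 * ref$n_tp[i] / n_gold),
                       ref$sens[i])
    }
  }
})

test_that("interval invariants hold across the (k, n) grid", {
  for (n in c(5, 12, 39, 57, 85)) {
    for (k in 0:n) {
      ci <- wald_ci(k, n)
      point <- round_half_up(100 * k / n)
      expect_true(ci[1] >= 0 && ci[2] <= 100)
      expect_true(ci[1] <= point && point <= ci[2])
    }
  }
  # width shrinks as n grows at fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- wald_ci(round(0.3 * n), n)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("contingency partitions the cohort and rejects bad input", {
  ids <- sprintf("P%02d", 1:85)
  gold <- data.frame(
    patient_id = ids,
    status = c(rep("oa_positive", 25), rep("oa_negative", 14),
               rep("oa_positive", 32), rep("oa_negative", 14)),
    stringsAsFactors = FALSE)
  dec <- stats::setNames(c(rep(TRUE, 39), rep(FALSE, 46)), ids)
  t <- contingency(dec, gold)
  expect_identical(unclass(t)[c("tp", "fp", "fn", "tn")],
                   list(tp = 25L, fp = 14L, fn = 32L, tn = 14L))

  # patient ordering does not matter
  t2 <- contingency(dec[sample(ids)], gold)
  expect_identical(unclass(t2), unclass(t))

  expect_identical(contingency(dec & FALSE, gold)$tp, 0L)
  perfect <- stats::setNames(gold$status == "oa_positive", ids)
  tp3 <- contingency(perfect, gold)
  expect_identical(tp3$fp + tp3$fn, 0L)

  expect_error(contingency(dec[-1], gold), "differ")
  gold$status[1] <- "indeterminate"
  expect_error(contingency(dec, gold), "indeterminate")
})

test_that("rounding is half away from zero", {
  expect_identical(round_half_up(49.05), 49.1)
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round_half_up(-0.25, 1), -0.3)
  expect_identical(round_half_up(52.5, 0), 53)
})

test_that("cohort summary handles trivial and degenerate inputs", {
  cs <- default_codesets()
  ev <- data.frame(patient_id = "P1", code = cs$knee_oa[1],
                   event_date = as.Date("2005-03-01"))
  co <- tiny_cohort(events = ev)
  co$patients$birth_year <- 1945L  # age 60 at 2005 index
  gold <- data.frame(patient_id = "P1", status = "oa_positive",
                     basis = "coded_imaging", stringsAsFactors = FALSE)
  s <- summarize_cohort(co, gold, cs)
  expect_identical(s$mean_age, 60)
  expect_identical(s$pct_women, 100)
  expect_identical(s$pct_oa_code, 100)
  expect_identical(s$pct_pain_code, 0)
  expect_identical(s$pct_gold_positive, 100)
  expect_error(summarize_cohort(new_cohort(), gold, cs), "empty")
})

test_that("validate_algorithms reproduces a perfect-test row", {
  fx <- build_row_fixture("one_oa_code", 20, 8, 8, 8)
  gold <- adjudicate_cohort(fx$cohort)
  dec <- evaluate_all(fx$cohort, list(fx$algorithm))
  val <- validate_algorithms(dec, gold)
  expect_identical(val$ppv, 100.0)
  expect_identical(val$sens, 100.0)
})
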