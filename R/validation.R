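#' Two-by-two contingency of algorithm decision vs gold standard
#'
#' @param decisions named logical vector (names = patient ids) for one
#'   algorithm.
#' @param gold data frame `patient_id, status` from [adjudicate_cohort()].
#'   Indeterminate patients must already have been excluded.
#' @return a list `tp, fp, fn, tn` with class `oa_twobytwo`.
#' @export
contingency <- function(decisions, gold) {
  if (!setequal(names(decisions), gold$patient_id) ||
      length(decisions) != nrow(gold)) {
    stop("decision and gold-standard patient sets differ", call. = FALSE)
  }
  if (any(gold$status == "indeterminate")) {
    stop("indeterminate gold-standard patients must be excluded before ",
         "building a contingency table", call. = FALSE)
  }
  g <- stats::setNames(gold$status == "oa_positive", gold$patient_id)
  g <- g[names(decisions)]
  structure(list(tp = sum(decisions & g), fp = sum(decisions & !g),
                 fn = sum(!decisions & g), tn = sum(!decisions & !g)),
            class = "oa_twobytwo")
}

#' Positive predictive value, percent
#'
#' `100 * tp / (tp + fp)`, rounded half away from zero to one decimal.
#' Undefined (no test positives) is reported as `NA`, never 0 or 100.
#'
#' @param t an `oa_twobytwo`.
#' @return numeric percent or `NA`.
#' @export
ppv <- function(t) {
  if (t$tp + t$fp == 0L) return(NA_real_)
  round_half_up(100 * t$tp / (t$tp + t$fp), 1)
}

#' Sensitivity, percent
#'
#' `100 * tp / (tp + fn)` (of those with disease, the share testing
#' positive), rounded half away from zero to one decimal; `NA` when there
#' are no gold positives.
#'
#' @param t an `oa_twobytwo`.
#' @return numeric percent or `NA`.
#' @export
sensitivity <- function(t) {
  if (t$tp + t$fn == 0L) return(NA_real_)
  round_half_up(100 * t$tp / (t$tp + t$fn), 1)
}

#' Wald 95% confidence interval for a proportion, percent scale
#'
#' Normal-approximation interval `p +/- z*sqrt(p(1-p)/n)` with
#' `z = qnorm(0.975)`, clipped to `[0, 100]` and rounded half away from
#' zero to one decimal. At `k = 0` or `k = n` the variance term vanishes
#' and the interval degenerates to the point estimate before clipping.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n > 0`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` in percent, or `c(NA, NA)` when `n = 0`.
#' @export
wald_ci <- function(k, n, level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  stopifnot(k >= 0, k <= n)
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(round_half_up(max(0, 100 * (p - half)), 1),
    round_half_up(min(100, 100 * (p + half)), 1))
}

#' Validate algorithms against the gold standard
#'
#' One row per algorithm: the number of patients satisfying the
#' definition, true positives among them, PPV and sensitivity with Wald
#' 95% confidence intervals — the layout of a published validation table.
#'
#' @param decisions logical decision matrix from [evaluate_all()].
#' @param gold data frame `patient_id, status` (no indeterminates).
#' @param labels optional named character vector mapping algorithm names to
#'   display labels.
#' @return data frame `algorithm, label, n_satisfying, n_tp, ppv, ppv_lo,
#'   ppv_hi, sens, sens_lo, sens_hi`.
#' @export
validate_algorithms <- function(decisions, gold, labels = NULL) {
  rows <- lapply(colnames(decisions), function(alg) {
    dec <- stats::setNames(decisions[, alg], rownames(decisions))
    t <- contingency(dec, gold)
    pci <- wald_ci(t$tp, t$tp + t$fp)
    sci <- wald_ci(t$tp, t$tp + t$fn)
    data.frame(algorithm = alg,
               label = unname((labels[alg]) %||% alg),
               n_satisfying = t$tp + t$fp, n_tp = t$tp,
               ppv = ppv(t), ppv_lo = pci[1], ppv_hi = pci[2],
               sens = sensitivity(t), sens_lo = sci[1], sens_hi = sci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary in the style of a baseline-characteristics table
#'
#' Mean (SD) age at index, percent women, percent with at least one OA
#' code, pain code, imaging code/report, and percent gold-standard
#' positive. Percentages are rounded to whole numbers, mean/SD of age to
#' one decimal.
#'
#' @param cohort a filtered `oa_cohort`.
#' @param gold data frame from [adjudicate_cohort()].
#' @param codesets an `oa_codesets` configuration.
#' @param criteria an `oa_criteria` (for index-date computation).
#' @return a one-row data frame.
#' @export
summarize_cohort <- function(cohort, gold, codesets = default_codesets(),
                             criteria = eligibility_criteria()) {
  p <- cohort$patients
  if (!nrow(p)) stop("cannot summarise an empty cohort", call. = FALSE)
  cat_ <- categorize_code(cohort$events$code, codesets)
  idx <- vapply(p$patient_id, function(id) {
    as.numeric(index_date(cohort$events[cohort$events$patient_id == id, ,
                                        drop = FALSE], codesets, criteria))
  }, numeric(1))
  ages <- as.integer(format(as.Date(idx, origin = "1970-01-01"), "%Y")) -
    p$birth_year
  has_cat <- function(ctg) {
    ids <- unique(cohort$events$patient_id[!is.na(cat_) & cat_ == ctg])
    mean(p$patient_id %in% ids)
  }
  has_imaging <- mean(p$patient_id %in%
    union(unique(cohort$events$patient_id[!is.na(cat_) & cat_ == "imaging"]),
          unique(cohort$imaging$patient_id[cohort$imaging$source == "coded"])))
  gpos <- mean(p$patient_id %in% gold$patient_id[gold$status == "oa_positive"])
  data.frame(
    n = nrow(p),
    mean_age = round_half_up(mean(ages, na.rm = TRUE), 1),
    sd_age = round_half_up(stats::sd(ages, na.rm = TRUE), 1),
    pct_women = round_half_up(100 * mean(p$sex == "female"), 0),
    pct_oa_code = round_half_up(100 * has_cat("knee_oa"), 0),
    pct_pain_code = round_half_up(100 * has_cat("knee_pain"), 0),
    pct_imaging = round_half_up(100 * has_imaging, 0),
    pct_gold_positive = round_half_up(100 * gpos, 0)
  )
}

#' Render a validation data frame as a fixed-width text table
#'
#' @param validation data frame from [validate_algorithms()].
#' @return character vector of lines, invisibly; also printed.
#' @export
format_validation_table <- function(validation) {
  fmt <- function(x, lo, hi) {
    ifelse(is.na(x), "--",
           sprintf("%.1f (%.1f, %.1f)", x, lo, hi))
  }
  df <- data.frame(
    Definition = validation$label,
    `N satisfying` = validation$n_satisfying,
    `N true positive` = validation$n_tp,
    `PPV (95% CI)` = fmt(validation$ppv, validation$ppv_lo, validation$ppv_hi),
    `Sensitivity (95% CI)` = fmt(validation$sens, validation$sens_lo,
                                 validation$sens_hi),
    check.names = FALSE
  )
  lines <- utils::capture.output(print(df, row.names = FALSE))
  cat(lines, sep = "\n")
  invisible(lines)
}
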