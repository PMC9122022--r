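#' Eligibility criteria
#'
#' Cohort-selection constants: adults aged 40-90 whose first knee OA or
#' knee pain code falls in the assessment period 2000-01-01..2015-05-31,
#' registered with their practice for at least a year before that index
#' date.
#'
#' @param assessment_start,assessment_end assessment period bounds.
#' @param min_age,max_age inclusive age bounds at the index date.
#' @param min_registration_days required registered days before index.
#' @return a list with class `oa_criteria`.
#' @export
eligibility_criteria <- function(assessment_start = as.Date("2000-01-01"),
                                 assessment_end = as.Date("2015-05-31"),
                                 min_age = 40, max_age = 90,
                                 min_registration_days = 365L) {
  stopifnot(assessment_start < assessment_end, min_age < max_age,
            min_registration_days >= 0)
  structure(list(assessment_start = as.Date(assessment_start),
                 assessment_end = as.Date(assessment_end),
                 min_age = min_age, max_age = max_age,
                 min_registration_days = as.integer(min_registration_days)),
            class = "oa_criteria")
}

#' Index date: first knee OA or knee pain code in the assessment period
#'
#' The index date anchors age, the registration look-back and the
#' TKR-before-index exclusion. Codes before the assessment period are
#' ignored; a same-day OA/pain tie is immaterial (the date is the index).
#'
#' @param events events data frame for one patient (`code`, `event_date`).
#' @param codesets an `oa_codesets` configuration.
#' @param criteria an `oa_criteria` object.
#' @return a `Date`, or `NA` if the patient has no qualifying code.
#' @export
index_date <- function(events, codesets,
                       criteria = eligibility_criteria()) {
  cat_ <- categorize_code(events$code, codesets)
  d <- events$event_date[!is.na(cat_) & cat_ %in% c("knee_oa", "knee_pain")]
  d <- d[d >= criteria$assessment_start & d <= criteria$assessment_end]
  if (!length(d)) return(as.Date(NA))
  min(d)
}

#' Eligibility of one patient at their index date
#'
#' Eligible iff age at index (index year minus birth year; anonymised
#' records carry birth year only) is within 40-90 and the patient was
#' registered for at least `min_registration_days` before the index date
#' with a registration spell overlapping the assessment period.
#'
#' @param patient one row of the patients table.
#' @param index the patient's index date.
#' @param criteria an `oa_criteria` object.
#' @return logical, with a character vector of failure reasons
#'   (`"age"`, `"registration"`) in attribute `"reasons"`.
#' @export
is_eligible <- function(patient, index, criteria = eligibility_criteria()) {
  stopifnot(!is.na(index))
  reasons <- character()
  age <- as.integer(format(as.Date(index), "%Y")) - patient$birth_year
  if (age < criteria$min_age || age > criteria$max_age) {
    reasons <- c(reasons, "age")
  }
  overlaps <- patient$registration_start <= criteria$assessment_end &&
    patient$registration_end >= criteria$assessment_start
  lookback <- days_between(patient$registration_start, index)
  if (!overlaps || lookback < criteria$min_registration_days) {
    reasons <- c(reasons, "registration")
  }
  structure(length(reasons) == 0L, reasons = reasons)
}

# fixed priority making the exclusion log deterministic when a patient has
# several exclusion conditions
EXCLUSION_PRIORITY <- c("ra", "gout", "pseudogout", "psoriatic_arthritis",
                        "tkr_before_index", "insufficient_data")

exclusion_reason_for_category <- c(
  exclusion_ra = "ra", exclusion_gout = "gout",
  exclusion_pseudogout = "pseudogout", exclusion_psa = "psoriatic_arthritis"
)

#' Apply the exclusion rules to a cohort
#'
#' A patient is excluded if any of the following holds:
#'
#' 1. a rheumatic-disorder category (RA, gout, pseudogout, psoriatic
#'    arthritis) has two or more codes separated by at least 7 days
#'    anywhere in the record;
#' 2. a total-knee-replacement code strictly before the index date;
#' 3. the gold standard cannot be evaluated: no questionnaire knee-pain
#'    answer AND no imaging report of any kind.
#'
#' One primary reason is logged per excluded patient using the fixed
#' priority RA > gout > pseudogout > psoriatic arthritis > TKR-before-index
#' > insufficient data.
#'
#' @param cohort an `oa_cohort` (all patients must have an index date).
#' @param codesets an `oa_codesets` configuration.
#' @param index_dates named `Date` vector (names = patient ids); computed
#'   from the events if omitted.
#' @param criteria an `oa_criteria` object.
#' @param min_separation_days separation required between the two
#'   rheumatic-disorder codes (default 7).
#' @return a list with `cohort` (retained patients only) and `outcomes`, a
#'   data frame `patient_id, excluded, reason` (`reason` is `"none"` for
#'   retained patients).
#' @export
apply_exclusions <- function(cohort, codesets = default_codesets(),
                             index_dates = NULL,
                             criteria = eligibility_criteria(),
                             min_separation_days = 7L) {
  p <- cohort$patients
  if (is.null(index_dates)) {
    index_dates <- vapply(p$patient_id, function(id) {
      as.numeric(index_date(cohort$events[cohort$events$patient_id == id, ,
                                          drop = FALSE],
                            codesets, criteria))
    }, numeric(1))
    index_dates <- as.Date(index_dates, origin = "1970-01-01")
    names(index_dates) <- p$patient_id
  }
  missing_idx <- setdiff(p$patient_id, names(index_dates))
  if (length(missing_idx)) {
    stop("no index date provided for: ", paste(missing_idx, collapse = ", "),
         call. = FALSE)
  }

  cat_ <- categorize_code(cohort$events$code, codesets)
  q <- cohort$questionnaire
  reason <- vapply(p$patient_id, function(id) {
    ev <- cohort$events[cohort$events$patient_id == id, , drop = FALSE]
    ec <- cat_[cohort$events$patient_id == id]
    for (ctg in RHEUMATIC_EXCLUSION_CATEGORIES) {
      d <- sort(ev$event_date[!is.na(ec) & ec == ctg])
      if (meets_pair_rule(d, min_separation_days, Inf)) {
        return(exclusion_reason_for_category[[ctg]])
      }
    }
    idx <- index_dates[[id]]
    tkr <- ev$event_date[!is.na(ec) & ec == "tkr"]
    if (!is.na(idx) && length(tkr) && any(tkr < idx)) {
      return("tkr_before_index")
    }
    pain_ans <- q$pain_over_6_weeks[q$patient_id == id]
    has_pain_answer <- length(pain_ans) > 0 && any(!is.na(pain_ans))
    has_reports <- any(cohort$imaging$patient_id == id)
    if (!has_pain_answer && !has_reports) return("insufficient_data")
    "none"
  }, character(1))

  outcomes <- data.frame(patient_id = p$patient_id,
                         excluded = reason != "none",
                         reason = unname(reason),
                         stringsAsFactors = FALSE)
  keep <- outcomes$patient_id[!outcomes$excluded]
  filtered <- new_cohort(
    p[p$patient_id %in% keep, , drop = FALSE],
    cohort$events[cohort$events$patient_id %in% keep, , drop = FALSE],
    cohort$imaging[cohort$imaging$patient_id %in% keep, , drop = FALSE],
    cohort$questionnaire[cohort$questionnaire$patient_id %in% keep, ,
                         drop = FALSE]
  )
  list(cohort = filtered, outcomes = outcomes)
}
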