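# Independent brute-force oracles. These deliberately re-derive the rule
# semantics by exhaustive enumeration and never call into the engine.

# any ordered pair of dates with gap in [sep, win]?
oracle_pair <- function(dates, sep, win = Inf) {
  d <- sort(as.numeric(dates))
  n <- length(d)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      gap <- d[j] - d[i]
      if (gap >= sep && gap <= win) return(TRUE)
    }
  }
  FALSE
}

# exhaustive subset enumeration of a count rule on one category
oracle_count_rule <- function(rule, dates, sep, win) {
  if (is.null(rule)) return(TRUE)
  d <- sort(as.numeric(dates))
  if (rule$type == "exactly_one") return(length(d) == 1)
  k <- rule$k
  if (length(d) < k) return(FALSE)
  if (k == 1) return(TRUE)
  for (sub in utils::combn(seq_along(d), k, simplify = FALSE)) {
    s <- d[sub]
    if ((max(s) - min(s)) <= win && all(diff(s) >= sep)) return(TRUE)
  }
  FALSE
}

# full algorithm semantics by enumeration, from raw category date vectors
oracle_algorithm <- function(alg, oa_dates, pain_dates, img_dates = numeric()) {
  win <- if (is.null(alg$window_days)) Inf else alg$window_days
  sep <- alg$min_separation_days
  cross <- !is.null(alg$oa_rule) && !is.null(alg$pain_rule) &&
    alg$oa_rule$type == "at_least" && alg$pain_rule$type == "at_least"
  if (cross) {
    ok <- FALSE
    for (o in as.numeric(oa_dates)) {
      for (p in as.numeric(pain_dates)) {
        if (abs(o - p) >= sep && abs(o - p) <= win) ok <- TRUE
      }
    }
    qual <- c(as.numeric(oa_dates), as.numeric(pain_dates))
  } else {
    ok <- oracle_count_rule(alg$oa_rule, oa_dates, sep, win) &&
      oracle_count_rule(alg$pain_rule, pain_dates, sep, win)
    qual <- c(if (!is.null(alg$oa_rule)) as.numeric(oa_dates),
              if (!is.null(alg$pain_rule)) as.numeric(pain_dates))
  }
  if (!ok) return(FALSE)
  if (is.null(alg$require_imaging_within_days)) return(TRUE)
  for (im in as.numeric(img_dates)) {
    for (q in qual) {
      if (abs(im - q) <= alg$require_imaging_within_days) return(TRUE)
    }
  }
  FALSE
}

# build a one-patient events table from day offsets relative to a base date
record_from_offsets <- function(oa = integer(), pain = integer(),
                                img = integer(),
                                base = as.Date("2005-01-01"),
                                codesets = default_codesets()) {
  mk <- function(offs, code) {
    if (!length(offs)) return(NULL)
    data.frame(patient_id = "P1", code = code, event_date = base + offs,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(oa, codesets$knee_oa[1]),
               mk(pain, codesets$knee_pain[1]),
               mk(img, codesets$imaging[1]))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), code = character(),
                      event_date = as.Date(character()),
                      stringsAsFactors = FALSE)
  }
  out
}

# minimal single-patient cohort for small hand-built cases
tiny_cohort <- function(events = NULL, pain_answer = TRUE,
                        imaging = NULL, id = "P1") {
  patients <- data.frame(patient_id = id, sex = "female",
                         birth_year = 1945L,
                         registration_start = as.Date("1998-01-01"),
                         registration_end = as.Date("2016-12-31"),
                         stringsAsFactors = FALSE)
  q <- data.frame(patient_id = id, pain_over_6_weeks = pain_answer,
                  gp_cause_of_pain = NA_character_, stringsAsFactors = FALSE)
  new_cohort(patients,
             events %||% oaphen:::empty_events(),
             imaging %||% oaphen:::empty_imaging(),
             q)
}

make_report <- function(id = "P1", date = as.Date("2005-01-01"),
                        definite_osteophytes = FALSE,
                        joint_space_narrowing = FALSE, sclerosis = FALSE,
                        tibial_spiking = FALSE, impression_oa = FALSE,
                        source = "coded") {
  data.frame(patient_id = id, report_date = date, modality = "xray",
             definite_osteophytes = definite_osteophytes,
             joint_space_narrowing = joint_space_narrowing,
             sclerosis = sclerosis, tibial_spiking = tibial_spiking,
             impression_oa = impression_oa, source = source,
             report_text = NA_character_, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
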