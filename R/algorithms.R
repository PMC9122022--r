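#' Declarative case-identification algorithms
#'
#' An algorithm definition is a small temporal rule over a patient's coded
#' record:
#'
#' * a count rule per code category — `exactly_one` (exactly one code of
#'   that category in the whole record) or `at_least(k)`;
#' * an optional time window in days (`NULL` means the whole record);
#' * a minimum separation in days between the codes of a multi-code rule
#'   (default 7 — repeat codes at the same GP visit do not count twice);
#' * an optional imaging-proximity requirement: an imaging code or report
#'   within so many days (either side) of a qualifying diagnosis code.
#'
#' When both an OA and a pain rule are present (both `at_least(1)`), the
#' window and separation apply across the two categories: some OA code and
#' some pain code must be `min_separation_days` to `window_days` apart.
#'
#' @param name machine name (used as the decision-matrix column).
#' @param label human-readable row label for reports.
#' @param oa_rule,pain_rule `NULL`, `"exactly_one"`, or a list
#'   `list(at_least = k)`.
#' @param window_days window length in days or `NULL`.
#' @param min_separation_days minimum separation between paired codes.
#' @param require_imaging_within_days imaging-proximity bound in days or
#'   `NULL`.
#' @return an `oa_algorithm` object.
#' @export
algorithm_definition <- function(name, label = name,
                                 oa_rule = NULL, pain_rule = NULL,
                                 window_days = NULL,
                                 min_separation_days = 7L,
                                 require_imaging_within_days = NULL) {
  norm <- function(rule) {
    if (is.null(rule)) return(NULL)
    if (identical(rule, "exactly_one")) return(list(type = "exactly_one"))
    if (is.list(rule) && !is.null(rule$at_least)) {
      k <- as.integer(rule$at_least)
      stopifnot(k >= 1)
      return(list(type = "at_least", k = k))
    }
    stop("count rule must be NULL, 'exactly_one' or list(at_least = k)",
         call. = FALSE)
  }
  oa_rule <- norm(oa_rule); pain_rule <- norm(pain_rule)
  if (is.null(oa_rule) && is.null(pain_rule)) {
    stop("at least one count rule must be present", call. = FALSE)
  }
  if (!is.null(window_days) && window_days <= min_separation_days) {
    stop("window_days must exceed min_separation_days", call. = FALSE)
  }
  structure(list(name = name, label = label,
                 oa_rule = oa_rule, pain_rule = pain_rule,
                 window_days = if (is.null(window_days)) NULL
                               else as.integer(window_days),
                 min_separation_days = as.integer(min_separation_days),
                 require_imaging_within_days =
                   if (is.null(require_imaging_within_days)) NULL
                   else as.integer(require_imaging_within_days)),
            class = "oa_algorithm")
}

#' The eight published algorithms (plus imaging-restricted variants)
#'
#' Six months is fixed at 183 days, twelve months at 365, two years at 730;
#' month arithmetic is never used so results are reproducible. With
#' `imaging_variants = TRUE` each algorithm is duplicated with an `_img`
#' suffix and a two-year imaging-proximity requirement, which restricts the
#' analysis to patients with documented imaging near a diagnosis code.
#'
#' @param imaging_variants also return the imaging-restricted variants.
#' @param mixed_rule_separation_days separation required between the OA and
#'   pain codes of the combination rules (default 7; set 0 to allow a
#'   same-day OA + pain pair).
#' @return a named list of `oa_algorithm` objects.
#' @export
default_algorithms <- function(imaging_variants = FALSE,
                               mixed_rule_separation_days = 7L) {
  base <- list(
    algorithm_definition("one_oa_code", "One OA code",
                         oa_rule = "exactly_one"),
    algorithm_definition("one_pain_code", "One knee pain code",
                         pain_rule = "exactly_one"),
    algorithm_definition("oa2_6mo", ">=2 OA codes within 6 months",
                         oa_rule = list(at_least = 2), window_days = 183L),
    algorithm_definition("pain2_6mo",
                         ">=2 knee pain codes within 6 months",
                         pain_rule = list(at_least = 2), window_days = 183L),
    algorithm_definition("oa_pain_6mo",
                         ">=1 OA and >=1 knee pain code within 6 months",
                         oa_rule = list(at_least = 1),
                         pain_rule = list(at_least = 1),
                         window_days = 183L,
                         min_separation_days = mixed_rule_separation_days),
    algorithm_definition("oa2_12mo", ">=2 OA codes within 12 months",
                         oa_rule = list(at_least = 2), window_days = 365L),
    algorithm_definition("pain2_12mo",
                         ">=2 knee pain codes within 12 months",
                         pain_rule = list(at_least = 2), window_days = 365L),
    algorithm_definition("oa_pain_12mo",
                         ">=1 OA and >=1 knee pain code within 12 months",
                         oa_rule = list(at_least = 1),
                         pain_rule = list(at_least = 1),
                         window_days = 365L,
                         min_separation_days = mixed_rule_separation_days)
  )
  names(base) <- vapply(base, `[[`, "", "name")
  if (!imaging_variants) return(base)
  img <- lapply(base, function(a) {
    a$name <- paste0(a$name, "_img")
    a$label <- paste0(a$label, " + imaging within 2 years")
    a$require_imaging_within_days <- 730L
    a
  })
  names(img) <- vapply(img, `[[`, "", "name")
  c(base, img)
}

#' Read / write algorithm definitions as YAML
#' @param path YAML file: a list of entries mirroring
#'   [algorithm_definition()] arguments (`at_least` rules written as
#'   `{at_least: k}`).
#' @return `read_algorithms()` returns a named list of `oa_algorithm`s.
#' @export
read_algorithms <- function(path) {
  raw <- yaml::read_yaml(path)
  algs <- lapply(raw, function(a) {
    fix <- function(r) {
      if (is.null(r)) NULL
      else if (identical(r, "exactly_one")) "exactly_one"
      else list(at_least = r$at_least)
    }
    algorithm_definition(a$name, a$label %||% a$name,
                         oa_rule = fix(a$oa_rule),
                         pain_rule = fix(a$pain_rule),
                         window_days = a$window_days,
                         min_separation_days = a$min_separation_days %||% 7L,
                         require_imaging_within_days =
                           a$require_imaging_within_days)
  })
  names(algs) <- vapply(algs, `[[`, "", "name")
  algs
}

#' @rdname read_algorithms
#' @param algorithms named list of `oa_algorithm` objects.
#' @export
write_algorithms <- function(algorithms, path) {
  ser <- lapply(unname(algorithms), function(a) {
    out <- list(name = a$name, label = a$label)
    r <- function(rule) {
      if (is.null(rule)) NULL
      else if (rule$type == "exactly_one") "exactly_one"
      else list(at_least = rule$k)
    }
    out$oa_rule <- r(a$oa_rule)
    out$pain_rule <- r(a$pain_rule)
    out$window_days <- a$window_days
    out$min_separation_days <- a$min_separation_days
    out$require_imaging_within_days <- a$require_imaging_within_days
    out[!vapply(out, is.null, TRUE)]
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Pair rule on a sorted date vector
#'
#' `TRUE` iff two of the dates are at least `min_separation_days` and at
#' most `window_days` apart. Bounds are inclusive: with a 7-day separation,
#' codes on day 0 and day 7 qualify.
#'
#' @param dates sorted `Date` (or numeric day) vector.
#' @param min_separation_days,window_days inclusive bounds on the pair gap
#'   (`window_days = Inf` for whole-record rules).
#' @return logical scalar.
#' @export
meets_pair_rule <- function(dates, min_separation_days, window_days = Inf) {
  n <- length(dates)
  if (n < 2L) return(FALSE)
  d <- as.numeric(dates)
  # sorted input: for each i it suffices to check gaps to later dates
  for (i in seq_len(n - 1L)) {
    gaps <- d[(i + 1L):n] - d[i]
    if (any(gaps >= min_separation_days & gaps <= window_days)) return(TRUE)
  }
  FALSE
}

# Maximum number of dates selectable from sorted `d` such that all chosen
# dates lie within `window` of the first chosen one and consecutive chosen
# dates are >= sep apart. Greedy earliest-first is optimal for this
# interval-scheduling shape.
max_codes_in_window <- function(d, sep, window) {
  d <- as.numeric(d)
  n <- length(d)
  if (!n) return(0L)
  best <- 1L
  for (i in seq_len(n)) {
    lim <- d[i] + window
    cnt <- 1L
    last <- d[i]
    j <- i + 1L
    while (j <= n && d[j] <= lim) {
      if (d[j] - last >= sep) {
        cnt <- cnt + 1L
        last <- d[j]
      }
      j <- j + 1L
    }
    best <- max(best, cnt)
  }
  best
}

#' Evaluate one algorithm on one patient record
#'
#' @param events the patient's coded events (`code`, `event_date`).
#' @param algorithm an `oa_algorithm`.
#' @param codesets an `oa_codesets` configuration.
#' @param imaging optional imaging-report data frame for the patient; its
#'   coded report dates count as imaging evidence alongside imaging-category
#'   code events when the algorithm carries an imaging-proximity
#'   requirement.
#' @return logical decision.
#' @export
apply_algorithm <- function(events, algorithm, codesets = default_codesets(),
                            imaging = NULL) {
  cat_ <- categorize_code(events$code, codesets)
  oa_dates <- sort(events$event_date[!is.na(cat_) & cat_ == "knee_oa"])
  pain_dates <- sort(events$event_date[!is.na(cat_) & cat_ == "knee_pain"])
  win <- algorithm$window_days %||% Inf
  sep <- algorithm$min_separation_days

  oa <- algorithm$oa_rule
  pain <- algorithm$pain_rule
  cross_pair <- !is.null(oa) && !is.null(pain) &&
    oa$type == "at_least" && pain$type == "at_least"

  qualifying <- as.Date(character())
  if (cross_pair) {
    # combination rule: one OA date and one pain date sep..win apart
    ok <- FALSE
    if (length(oa_dates) && length(pain_dates)) {
      gaps <- abs(outer(as.numeric(oa_dates), as.numeric(pain_dates), "-"))
      ok <- any(gaps >= sep & gaps <= win)
    }
    if (ok) qualifying <- c(oa_dates, pain_dates)
  } else {
    eval_single <- function(rule, dates) {
      if (is.null(rule)) return(TRUE)
      if (rule$type == "exactly_one") return(length(dates) == 1L)
      if (rule$k == 1L) return(length(dates) >= 1L)
      if (rule$k == 2L) return(meets_pair_rule(dates, sep, win))
      max_codes_in_window(dates, sep, win) >= rule$k
    }
    ok <- eval_single(oa, oa_dates) && eval_single(pain, pain_dates)
    if (ok) {
      if (!is.null(oa)) qualifying <- c(qualifying, oa_dates)
      if (!is.null(pain)) qualifying <- c(qualifying, pain_dates)
    }
  }
  if (!ok) return(FALSE)

  bound <- algorithm$require_imaging_within_days
  if (is.null(bound)) return(TRUE)
  img_dates <- events$event_date[!is.na(cat_) & cat_ == "imaging"]
  if (!is.null(imaging) && nrow(imaging)) {
    img_dates <- c(img_dates,
                   imaging$report_date[imaging$source == "coded"])
  }
  if (!length(img_dates) || !length(qualifying)) return(FALSE)
  gaps <- abs(outer(as.numeric(img_dates), as.numeric(qualifying), "-"))
  any(gaps <= bound)
}

#' Evaluate a set of algorithms on a whole cohort
#'
#' @param cohort an `oa_cohort` (already filtered for eligibility and
#'   exclusions).
#' @param algorithms named list of `oa_algorithm` objects.
#' @param codesets an `oa_codesets` configuration.
#' @return a logical matrix, patients in rows (rownames = patient ids),
#'   algorithms in columns.
#' @export
evaluate_all <- function(cohort, algorithms = default_algorithms(),
                         codesets = default_codesets()) {
  ids <- cohort$patients$patient_id
  m <- matrix(FALSE, nrow = length(ids), ncol = length(algorithms),
              dimnames = list(ids, vapply(algorithms, `[[`, "", "name")))
  ev_split <- split(cohort$events, cohort$events$patient_id)
  im_split <- split(cohort$imaging, cohort$imaging$patient_id)
  for (id in ids) {
    ev <- ev_split[[id]] %||% empty_events()
    im <- im_split[[id]] %||% empty_imaging()
    for (j in seq_along(algorithms)) {
      m[id, j] <- apply_algorithm(ev, algorithms[[j]], codesets, im)
    }
  }
  m
}
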