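#' Imaging-report positivity for knee osteoarthritis
#'
#' A report demonstrates OA iff it shows definite osteophytes, joint space
#' narrowing, or the radiologist's impression states OA / degenerative
#' arthritis. Sclerosis or tibial spiking alone are NOT sufficient.
#'
#' @param report one imaging-report row (list or single-row data frame with
#'   the boolean findings flags).
#' @return logical.
#' @export
imaging_consistent_with_oa <- function(report) {
  isTRUE(as.logical(report$definite_osteophytes)) ||
    isTRUE(as.logical(report$joint_space_narrowing)) ||
    isTRUE(as.logical(report$impression_oa))
}

#' Map a canned report string to findings flags
#'
#' A deliberately thin keyword mapper used only for the synthetic
#' generator's report strings — there is no NLP here, and it is not meant
#' for free-text radiology reports (it does not handle negation).
#'
#' @param text character scalar.
#' @return named logical vector with the five findings flags.
#' @export
report_flags_from_text <- function(text) {
  t <- tolower(text)
  c(definite_osteophytes = grepl("definite osteophyte", t),
    joint_space_narrowing = grepl("joint space narrowing|\\bjsn\\b", t),
    sclerosis = grepl("sclerosis", t),
    tibial_spiking = grepl("tibial spiking", t),
    impression_oa = grepl("impression[^.]*(osteoarthritis|degenerative arthritis)", t))
}

report_text_from_flags <- function(flags) {
  bits <- c(
    if (isTRUE(flags[["definite_osteophytes"]])) "definite osteophytes",
    if (isTRUE(flags[["joint_space_narrowing"]])) "joint space narrowing",
    if (isTRUE(flags[["sclerosis"]])) "sclerosis",
    if (isTRUE(flags[["tibial_spiking"]])) "tibial spiking"
  )
  txt <- if (length(bits)) paste("Findings:", paste(bits, collapse = ", "), ".")
         else "Findings: no significant abnormality."
  if (isTRUE(flags[["impression_oa"]])) {
    txt <- paste(txt, "Impression: osteoarthritis of the knee.")
  }
  txt
}

#' Adjudicate gold-standard knee OA status for one patient
#'
#' The reference standard is symptomatic, imaging-confirmed disease: knee
#' pain lasting more than six weeks (GP questionnaire) AND at least one
#' x-ray/MRI report demonstrating OA ([imaging_consistent_with_oa()]).
#' Reports transcribed from GP notes count the same as coded reports.
#' Status is `indeterminate` only when the pain answer is missing and no
#' report of any kind is available; a confirmed-pain patient with no
#' qualifying imaging is negative.
#'
#' @param reports imaging-report rows for the patient (coded and
#'   GP-transcribed; may have zero rows).
#' @param pain_over_6_weeks logical or `NA` (missing answer).
#' @return a list `status` (`"oa_positive"`, `"oa_negative"`,
#'   `"indeterminate"`) and `basis` (`"coded_imaging"`,
#'   `"gp_transcribed_imaging"`, `"none"`).
#' @export
adjudicate <- function(reports, pain_over_6_weeks) {
  n <- if (is.null(reports)) 0L else nrow(reports)
  qual <- logical(n)
  for (i in seq_len(n)) {
    qual[i] <- imaging_consistent_with_oa(reports[i, , drop = FALSE])
  }
  basis <- "none"
  if (any(qual)) {
    basis <- if (any(qual & reports$source == "coded")) "coded_imaging"
             else "gp_transcribed_imaging"
  }
  pain <- pain_over_6_weeks
  status <- if (isTRUE(pain) && any(qual)) {
    "oa_positive"
  } else if (is.na(pain) && n == 0L) {
    "indeterminate"
  } else {
    "oa_negative"
  }
  if (status != "oa_positive") basis <- "none"
  list(status = status, basis = basis)
}

#' Adjudicate every patient in a cohort
#'
#' @param cohort an `oa_cohort` (exclusions already applied).
#' @return data frame `patient_id, status, basis`.
#' @export
adjudicate_cohort <- function(cohort) {
  empty <- data.frame(patient_id = character(), status = character(),
                      basis = character(), stringsAsFactors = FALSE)
  if (!nrow(cohort$patients)) return(empty)
  q <- cohort$questionnaire
  im_split <- split(cohort$imaging, cohort$imaging$patient_id)
  res <- lapply(cohort$patients$patient_id, function(id) {
    pain <- q$pain_over_6_weeks[q$patient_id == id]
    pain <- if (length(pain)) pain[1] else NA
    a <- adjudicate(im_split[[id]] %||% empty_imaging(), pain)
    data.frame(patient_id = id, status = a$status, basis = a$basis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
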