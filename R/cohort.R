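#' Longitudinal cohort container
#'
#' An `oa_cohort` bundles the four delimited tables of a coded primary-care
#' extract:
#'
#' * `patients`: `patient_id, sex, birth_year, registration_start,
#'   registration_end`
#' * `events`: `patient_id, code, event_date` — one dated clinical code per
#'   row, the atom the rule engine consumes
#' * `imaging`: `patient_id, report_date, modality, definite_osteophytes,
#'   joint_space_narrowing, sclerosis, tibial_spiking, impression_oa,
#'   source, report_text` — structured findings from x-ray/MRI reports;
#'   `source` is `"coded"` for reports tied to an imaging code in the record
#'   and `"gp_transcribed"` for findings transcribed from GP notes or
#'   questionnaires (the two are interchangeable for gold-standard
#'   adjudication)
#' * `questionnaire`: `patient_id, pain_over_6_weeks, gp_cause_of_pain` —
#'   the GP questionnaire on the cause and duration of knee pain; missing
#'   answers stay missing, never imputed
#'
#' Every `patient_id` in the satellite tables must exist in `patients`.
#'
#' @param patients,events,imaging,questionnaire data frames as above.
#' @return a validated `oa_cohort` object.
#' @export
new_cohort <- function(patients = empty_patients(),
                       events = empty_events(),
                       imaging = empty_imaging(),
                       questionnaire = empty_questionnaire()) {
  rownames(patients) <- rownames(events) <- rownames(imaging) <-
    rownames(questionnaire) <- NULL
  cohort <- structure(
    list(patients = patients, events = events,
         imaging = imaging, questionnaire = questionnaire),
    class = "oa_cohort"
  )
  validate_cohort(cohort)
}

empty_patients <- function() {
  data.frame(patient_id = character(), sex = character(),
             birth_year = integer(),
             registration_start = as.Date(character()),
             registration_end = as.Date(character()),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(patient_id = character(), code = character(),
             event_date = as.Date(character()), stringsAsFactors = FALSE)
}

empty_imaging <- function() {
  data.frame(patient_id = character(), report_date = as.Date(character()),
             modality = character(), definite_osteophytes = logical(),
             joint_space_narrowing = logical(), sclerosis = logical(),
             tibial_spiking = logical(), impression_oa = logical(),
             source = character(), report_text = character(),
             stringsAsFactors = FALSE)
}

empty_questionnaire <- function() {
  data.frame(patient_id = character(), pain_over_6_weeks = logical(),
             gp_cause_of_pain = character(), stringsAsFactors = FALSE)
}

#' Validate an `oa_cohort`
#'
#' Enforces the container invariants: unique patient ids, valid sex codes,
#' registration_start <= registration_end, plausible birth years (age 0-120
#' at registration start), event dates within 1900-01-01..2100-01-01,
#' non-empty codes, and referential integrity of all satellite tables.
#'
#' @param cohort an `oa_cohort`.
#' @return the cohort, invisibly validated.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  if (anyDuplicated(p$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  if (nrow(p)) {
    if (!all(p$sex %in% c("female", "male"))) {
      stop("sex must be 'female' or 'male'", call. = FALSE)
    }
    if (any(p$registration_start > p$registration_end)) {
      stop("registration_start after registration_end for: ",
           paste(p$patient_id[p$registration_start > p$registration_end],
                 collapse = ", "), call. = FALSE)
    }
    age0 <- as.integer(format(p$registration_start, "%Y")) - p$birth_year
    if (any(age0 < 0 | age0 > 120)) {
      stop("implausible birth_year (age outside 0-120 at registration) for: ",
           paste(p$patient_id[age0 < 0 | age0 > 120], collapse = ", "),
           call. = FALSE)
    }
  }
  e <- cohort$events
  if (nrow(e)) {
    if (any(!nzchar(e$code))) stop("empty code in events table", call. = FALSE)
    if (any(e$event_date < as.Date("1900-01-01") |
            e$event_date > as.Date("2100-01-01"))) {
      stop("event_date outside 1900-01-01..2100-01-01", call. = FALSE)
    }
  }
  for (tbl in c("events", "imaging", "questionnaire")) {
    orphans <- setdiff(cohort[[tbl]]$patient_id, p$patient_id)
    if (length(orphans)) {
      stop(sprintf("patient_id in %s not present in patients: %s",
                   tbl, paste(sort(unique(orphans)), collapse = ", ")),
           call. = FALSE)
    }
  }
  cohort
}

#' @export
print.oa_cohort <- function(x, ...) {
  cat("<oa_cohort>", nrow(x$patients), "patients,",
      nrow(x$events), "coded events,",
      nrow(x$imaging), "imaging reports,",
      nrow(x$questionnaire), "questionnaire responses\n")
  invisible(x)
}

#' Read a cohort from delimited files
#'
#' Reads the four CSV tables (see [new_cohort()] for schemas), parses
#' ISO-8601 dates with errors that name file, row and column, and validates
#' referential integrity. The imaging columns `source` and `report_text`
#' are optional on input (`source` defaults to `"coded"`).
#'
#' @param patients_path,events_path,imaging_path,questionnaire_path CSV
#'   file paths.
#' @return an `oa_cohort`.
#' @export
read_cohort <- function(patients_path, events_path, imaging_path,
                        questionnaire_path) {
  rd <- function(path) {
    utils::read.csv(path, colClasses = "character",
                    stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("'%s' is missing columns: %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }

  p <- rd(patients_path)
  need(p, c("patient_id", "sex", "birth_year",
            "registration_start", "registration_end"), patients_path)
  patients <- data.frame(
    patient_id = p$patient_id, sex = p$sex,
    birth_year = as.integer(p$birth_year),
    registration_start = parse_date_column(p$registration_start,
                                           patients_path, "registration_start"),
    registration_end = parse_date_column(p$registration_end,
                                         patients_path, "registration_end"),
    stringsAsFactors = FALSE
  )

  e <- rd(events_path)
  need(e, c("patient_id", "code", "event_date"), events_path)
  events <- data.frame(
    patient_id = e$patient_id, code = e$code,
    event_date = if (nrow(e)) parse_date_column(e$event_date, events_path,
                                                "event_date")
                 else as.Date(character()),
    stringsAsFactors = FALSE
  )

  im <- rd(imaging_path)
  need(im, c("patient_id", "report_date", "modality", "definite_osteophytes",
             "joint_space_narrowing", "sclerosis", "tibial_spiking",
             "impression_oa"), imaging_path)
  imaging <- data.frame(
    patient_id = im$patient_id,
    report_date = if (nrow(im)) parse_date_column(im$report_date, imaging_path,
                                                  "report_date")
                  else as.Date(character()),
    modality = im$modality,
    definite_osteophytes = parse_flag_column(im$definite_osteophytes,
                                             imaging_path, "definite_osteophytes"),
    joint_space_narrowing = parse_flag_column(im$joint_space_narrowing,
                                              imaging_path, "joint_space_narrowing"),
    sclerosis = parse_flag_column(im$sclerosis, imaging_path, "sclerosis"),
    tibial_spiking = parse_flag_column(im$tibial_spiking, imaging_path,
                                       "tibial_spiking"),
    impression_oa = parse_flag_column(im$impression_oa, imaging_path,
                                      "impression_oa"),
    source = if ("source" %in% names(im)) im$source
             else rep("coded", nrow(im)),
    report_text = if ("report_text" %in% names(im)) {
                    ifelse(nzchar(im$report_text), im$report_text,
                           NA_character_)
                  } else rep(NA_character_, nrow(im)),
    stringsAsFactors = FALSE
  )
  bad_src <- setdiff(imaging$source, c("coded", "gp_transcribed"))
  if (length(bad_src)) {
    stop(sprintf("invalid imaging source in '%s': %s", imaging_path,
                 paste(bad_src, collapse = ", ")), call. = FALSE)
  }

  q <- rd(questionnaire_path)
  need(q, c("patient_id", "pain_over_6_weeks", "gp_cause_of_pain"),
       questionnaire_path)
  questionnaire <- data.frame(
    patient_id = q$patient_id,
    pain_over_6_weeks = parse_flag_column(q$pain_over_6_weeks,
                                          questionnaire_path,
                                          "pain_over_6_weeks", allow_na = TRUE),
    gp_cause_of_pain = ifelse(is.na(q$gp_cause_of_pain) |
                                !nzchar(trimws(q$gp_cause_of_pain)),
                              NA_character_, q$gp_cause_of_pain),
    stringsAsFactors = FALSE
  )

  new_cohort(patients, events, imaging, questionnaire)
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `patients.csv`, `events.csv`, `imaging.csv` and
#' `questionnaire.csv`; boolean flags are serialised as 0/1 and dates as
#' ISO-8601, so a write/read round trip reproduces the cohort exactly.
#'
#' @param cohort an `oa_cohort`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  wr(cohort$patients, "patients.csv")
  wr(cohort$events, "events.csv")
  im <- cohort$imaging
  for (col in c("definite_osteophytes", "joint_space_narrowing", "sclerosis",
                "tibial_spiking", "impression_oa")) {
    im[[col]] <- as.integer(im[[col]])
  }
  wr(im, "imaging.csv")
  q <- cohort$questionnaire
  q$pain_over_6_weeks <- ifelse(is.na(q$pain_over_6_weeks), "",
                                as.integer(q$pain_over_6_weeks))
  wr(q, "questionnaire.csv")
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#' @param dir directory containing the four CSV tables.
#' @return an `oa_cohort`.
#' @export
read_cohort_dir <- function(dir) {
  read_cohort(file.path(dir, "patients.csv"),
              file.path(dir, "events.csv"),
              file.path(dir, "imaging.csv"),
              file.path(dir, "questionnaire.csv"))
}
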