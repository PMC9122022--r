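#' Synthetic cohort generator parameters
#'
#' Defaults encode the marginal structure of the validation sample: adults
#' 40-90, mean (SD) age 63.8 (11.1), 53% women, gold-standard knee-OA
#' prevalence 67%, 60% of patients with at least one OA code, 78% with at
#' least one pain code, 73% with imaging codes. Because cohort selection
#' requires an index (OA or pain) code, the per-status code probabilities
#' are parameterised as: probability of carrying OA codes given case /
#' control status (0.70 / 0.40, marginal 0.60 at prevalence 0.67); a
#' patient without OA codes always carries pain codes, and one with OA
#' codes carries pain codes with probability 0.70 / 0.40 (case / control),
#' giving a 0.78 pain marginal.
#'
#' @param n_patients number of patients to generate.
#' @param prevalence latent gold-standard knee-OA prevalence.
#' @param p_oa_code_given_case,p_oa_code_given_control probability of
#'   carrying one or more knee-OA codes by latent status.
#' @param p_pain_code_given_case,p_pain_code_given_control probability of
#'   carrying pain codes for patients who also carry OA codes (patients
#'   without OA codes always carry pain codes).
#' @param p_imaging probability of a coded imaging record.
#' @param p_gp_report_given_no_imaging probability that a patient without
#'   imaging codes still has report findings transcribed from GP notes.
#' @param p_imaging_oa_given_case,p_imaging_oa_given_control probability
#'   that a patient's imaging report demonstrates OA, by latent status.
#' @param p_pain_answer_given_case,p_pain_answer_given_control probability
#'   the GP questionnaire confirms knee pain >6 weeks, by latent status.
#' @param p_pain_missing probability the questionnaire pain answer is
#'   missing.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age-at-index
#'   distribution (years).
#' @param p_female probability of female sex.
#' @param lambda_extra_codes Poisson mean of additional codes per carried
#'   category beyond the first (gaps 7-320 days).
#' @param exclusion_rates named numeric vector of injection probabilities
#'   for `ra`, `gout`, `pseudogout`, `psa`, `tkr` (all 0 by default, so
#'   generated cohorts pass the exclusion filter untouched).
#' @param seed integer seed for the single pseudo-random stream.
#' @return a list with class `oa_generator_params`.
#' @export
generator_params <- function(n_patients,
                             prevalence = 0.67,
                             p_oa_code_given_case = 0.70,
                             p_oa_code_given_control = 0.40,
                             p_pain_code_given_case = 0.70,
                             p_pain_code_given_control = 0.40,
                             p_imaging = 0.73,
                             p_gp_report_given_no_imaging = 0.80,
                             p_imaging_oa_given_case = 0.92,
                             p_imaging_oa_given_control = 0.15,
                             p_pain_answer_given_case = 0.95,
                             p_pain_answer_given_control = 0.60,
                             p_pain_missing = 0.02,
                             age_mean = 63.8, age_sd = 11.1,
                             age_min = 40, age_max = 90,
                             p_female = 0.53,
                             lambda_extra_codes = 1.0,
                             exclusion_rates = c(ra = 0, gout = 0,
                                                 pseudogout = 0, psa = 0,
                                                 tkr = 0),
                             seed = 1L) {
  p <- as.list(environment())
  probs <- c(prevalence, p_oa_code_given_case, p_oa_code_given_control,
             p_pain_code_given_case, p_pain_code_given_control, p_imaging,
             p_gp_report_given_no_imaging, p_imaging_oa_given_case,
             p_imaging_oa_given_control, p_pain_answer_given_case,
             p_pain_answer_given_control, p_pain_missing, p_female,
             exclusion_rates)
  stopifnot(all(probs >= 0 & probs <= 1), n_patients >= 0,
            age_min < age_max, age_sd > 0)
  structure(p, class = "oa_generator_params")
}

# truncated-normal draw via inverse CDF on a uniform stream
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_report_flags <- function(qualifies) {
  if (qualifies) {
    pick <- sample(1:3, 1)  # which qualifying finding combination
    c(definite_osteophytes = pick %in% c(1, 3),
      joint_space_narrowing = pick %in% c(2, 3),
      sclerosis = stats::runif(1) < 0.3,
      tibial_spiking = stats::runif(1) < 0.15,
      impression_oa = stats::runif(1) < 0.7)
  } else {
    c(definite_osteophytes = FALSE, joint_space_narrowing = FALSE,
      sclerosis = stats::runif(1) < 0.3,
      tibial_spiking = stats::runif(1) < 0.15,
      impression_oa = FALSE)
  }
}

#' Generate a synthetic longitudinal cohort
#'
#' Emits a cohort with the marginal structure described in
#' [generator_params()]: every patient has an index code inside the
#' assessment period, registration spanning at least a year before it, a
#' latent gold-standard status driving code counts, imaging-report
#' findings and questionnaire answers, and (optionally) injected exclusion
#' conditions. All randomness flows from one seeded stream, so the same
#' seed reproduces the same cohort exactly.
#'
#' The latent status of each patient is returned in the `"latent"`
#' attribute (`patient_id`, `gold_case`) for parameter-recovery checks; it
#' is generator truth, not part of the cohort tables.
#'
#' @param params an `oa_generator_params` object.
#' @param codesets an `oa_codesets` configuration supplying code strings.
#' @return an `oa_cohort` with attribute `"latent"`.
#' @export
generate_cohort <- function(params, codesets = default_codesets()) {
  stopifnot(inherits(params, "oa_generator_params"))
  set.seed(params$seed)
  n <- params$n_patients
  if (n == 0L) return(new_cohort())

  idx_lo <- as.numeric(as.Date("2001-01-01"))
  idx_hi <- as.numeric(as.Date("2014-06-30"))

  ids <- sprintf("S%05d", seq_len(n))
  case <- stats::runif(n) < params$prevalence
  index <- as.Date(floor(stats::runif(n, idx_lo, idx_hi + 1)),
                   origin = "1970-01-01")
  age <- round(rtruncnorm(n, params$age_mean, params$age_sd,
                          params$age_min, params$age_max))
  birth_year <- as.integer(format(index, "%Y")) - age
  sex <- ifelse(stats::runif(n) < params$p_female, "female", "male")
  reg_start <- index - (365L + floor(stats::runif(n, 0, 1500)))
  reg_end <- as.Date("2015-06-01") + floor(stats::runif(n, 0, 500))

  patients <- data.frame(patient_id = ids, sex = sex,
                         birth_year = birth_year,
                         registration_start = reg_start,
                         registration_end = reg_end,
                         stringsAsFactors = FALSE)

  ev <- list(); im <- list(); qn <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    p_oa <- if (case[i]) params$p_oa_code_given_case
            else params$p_oa_code_given_control
    has_oa <- stats::runif(1) < p_oa
    p_pain <- if (case[i]) params$p_pain_code_given_case
              else params$p_pain_code_given_control
    has_pain <- if (!has_oa) TRUE else stats::runif(1) < p_pain

    cats <- c(if (has_oa) "knee_oa", if (has_pain) "knee_pain")
    first_cat <- if (length(cats) == 2L) cats[1L + (stats::runif(1) < 0.5)]
                 else cats
    for (ctg in cats) {
      start <- if (ctg == first_cat) index[i]
               else index[i] + floor(stats::runif(1, 0, 181))
      n_codes <- 1L + min(stats::rpois(1, params$lambda_extra_codes), 4L)
      # repeat consultations weeks to ~10 months apart, so the 6- vs
      # 12-month windows genuinely discriminate
      gaps <- floor(stats::runif(n_codes - 1L, 7, 321))
      dates <- start + cumsum(c(0, gaps))
      dates <- dates[dates <= reg_end[i]]
      if (!length(dates)) {
        stop("generation failed for patient ", id,
             ": no room for a ", ctg, " code inside the registration spell",
             call. = FALSE)
      }
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = id,
        code = sample(codesets[[ctg]], length(dates), replace = TRUE),
        event_date = dates, stringsAsFactors = FALSE)
    }

    # imaging: coded record, or GP-transcribed findings, or nothing
    has_img_code <- stats::runif(1) < params$p_imaging
    src <- if (has_img_code) "coded"
           else if (stats::runif(1) < params$p_gp_report_given_no_imaging)
             "gp_transcribed" else NA_character_
    if (!is.na(src)) {
      rdate <- index[i] + floor(stats::runif(1, -360, 361))
      if (src == "coded") {
        ev[[length(ev) + 1L]] <- data.frame(
          patient_id = id, code = sample(codesets$imaging, 1),
          event_date = rdate, stringsAsFactors = FALSE)
      }
      p_q <- if (case[i]) params$p_imaging_oa_given_case
             else params$p_imaging_oa_given_control
      flags <- draw_report_flags(stats::runif(1) < p_q)
      im[[length(im) + 1L]] <- data.frame(
        patient_id = id, report_date = rdate,
        modality = if (stats::runif(1) < 0.85) "xray" else "mri",
        definite_osteophytes = flags[["definite_osteophytes"]],
        joint_space_narrowing = flags[["joint_space_narrowing"]],
        sclerosis = flags[["sclerosis"]],
        tibial_spiking = flags[["tibial_spiking"]],
        impression_oa = flags[["impression_oa"]],
        source = src, report_text = report_text_from_flags(flags),
        stringsAsFactors = FALSE)
    }

    # GP questionnaire
    missing_ans <- stats::runif(1) < params$p_pain_missing
    p_yes <- if (case[i]) params$p_pain_answer_given_case
             else params$p_pain_answer_given_control
    pain_ans <- if (missing_ans) NA else stats::runif(1) < p_yes
    cause <- if (missing_ans) NA_character_
             else if (case[i] && stats::runif(1) < 0.8) "osteoarthritis"
             else sample(c("trauma", "other", "unknown"), 1)
    qn[[length(qn) + 1L]] <- data.frame(
      patient_id = id, pain_over_6_weeks = pain_ans,
      gp_cause_of_pain = cause, stringsAsFactors = FALSE)

    # exclusion-condition injection (off by default)
    er <- params$exclusion_rates
    excl_codes <- c(ra = "exclusion_ra", gout = "exclusion_gout",
                    pseudogout = "exclusion_pseudogout",
                    psa = "exclusion_psa")
    for (cond in names(excl_codes)) {
      if (stats::runif(1) < (er[[cond]] %||% 0)) {
        d1 <- index[i] + floor(stats::runif(1, 30, 301))
        d2 <- d1 + floor(stats::runif(1, 7, 101))
        ev[[length(ev) + 1L]] <- data.frame(
          patient_id = id,
          code = sample(codesets[[excl_codes[[cond]]]], 2, replace = TRUE),
          event_date = c(d1, d2), stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1) < (er[["tkr"]] %||% 0)) {
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = id, code = sample(codesets$tkr, 1),
        event_date = index[i] - floor(stats::runif(1, 30, 401)),
        stringsAsFactors = FALSE)
    }
  }

  cohort <- new_cohort(
    patients,
    if (length(ev)) do.call(rbind, ev) else empty_events(),
    if (length(im)) do.call(rbind, im) else empty_imaging(),
    if (length(qn)) do.call(rbind, qn) else empty_questionnaire()
  )
  attr(cohort, "latent") <- data.frame(patient_id = ids, gold_case = case,
                                       stringsAsFactors = FALSE)
  cohort
}

#' Deterministic per-row validation fixture
#'
#' Builds a cohort of `n_total` eligible patients in which exactly
#' `n_satisfying` satisfy the named algorithm, `n_tp` of those are
#' gold-standard positive, and `n_gold_positive` patients are
#' gold-positive overall. Qualifying code pairs are laid out at day
#' offsets 0/30 for six-month windows and 0/300 for twelve-month windows;
#' filler patients carry a single non-triggering index code. Every patient
#' carries a coded imaging report (and an imaging code) at index, so the
#' fixture doubles as the imaging-restricted subcohort for `_img`
#' algorithm variants. No randomness is involved.
#'
#' @param name algorithm name (one of the [default_algorithms()] names,
#'   with or without the `_img` suffix).
#' @param n_total,n_gold_positive,n_satisfying,n_tp integer row counts.
#' @param codesets an `oa_codesets` configuration.
#' @return list with `cohort`, the target `algorithm` object, and
#'   `expected` (an `oa_twobytwo`).
#' @export
build_row_fixture <- function(name, n_total, n_gold_positive, n_satisfying,
                              n_tp, codesets = default_codesets()) {
  if (n_tp > min(n_satisfying, n_gold_positive) ||
      n_satisfying > n_total || n_gold_positive > n_total ||
      (n_gold_positive - n_tp) > (n_total - n_satisfying)) {
    stop("infeasible row fixture: counts are mutually inconsistent",
         call. = FALSE)
  }
  algorithms <- default_algorithms(imaging_variants = TRUE)
  if (!name %in% names(algorithms)) {
    stop("unknown algorithm: ", name, call. = FALSE)
  }
  algorithm <- algorithms[[name]]
  base <- sub("_img$", "", name)

  idx <- as.Date("2005-03-01")
  oa_code <- codesets$knee_oa[1]
  pain_code <- codesets$knee_pain[1]
  img_code <- codesets$imaging[1]
  pattern <- switch(base,
    one_oa_code  = data.frame(code = oa_code, off = 0),
    one_pain_code = data.frame(code = pain_code, off = 0),
    oa2_6mo      = data.frame(code = oa_code, off = c(0, 30)),
    pain2_6mo    = data.frame(code = pain_code, off = c(0, 30)),
    oa_pain_6mo  = data.frame(code = c(oa_code, pain_code), off = c(0, 30)),
    oa2_12mo     = data.frame(code = oa_code, off = c(0, 300)),
    pain2_12mo   = data.frame(code = pain_code, off = c(0, 300)),
    oa_pain_12mo = data.frame(code = c(oa_code, pain_code), off = c(0, 300))
  )
  filler_code <- if (base == "one_pain_code") oa_code else pain_code

  ids <- sprintf("F%03d", seq_len(n_total))
  gold_pos <- c(rep(TRUE, n_tp),
                rep(FALSE, n_satisfying - n_tp),
                rep(TRUE, n_gold_positive - n_tp),
                rep(FALSE, n_total - n_satisfying - (n_gold_positive - n_tp)))

  ev <- lapply(seq_len(n_total), function(i) {
    if (i <= n_satisfying) {
      codes <- pattern$code; dates <- idx + pattern$off
    } else {
      codes <- filler_code; dates <- idx
    }
    data.frame(patient_id = ids[i],
               code = c(codes, img_code),
               event_date = c(dates, idx), stringsAsFactors = FALSE)
  })
  im <- lapply(seq_len(n_total), function(i) {
    flags <- if (gold_pos[i]) {
      c(definite_osteophytes = TRUE, joint_space_narrowing = TRUE,
        sclerosis = FALSE, tibial_spiking = FALSE, impression_oa = TRUE)
    } else {
      c(definite_osteophytes = FALSE, joint_space_narrowing = FALSE,
        sclerosis = TRUE, tibial_spiking = FALSE, impression_oa = FALSE)
    }
    data.frame(patient_id = ids[i], report_date = idx, modality = "xray",
               definite_osteophytes = flags[["definite_osteophytes"]],
               joint_space_narrowing = flags[["joint_space_narrowing"]],
               sclerosis = flags[["sclerosis"]],
               tibial_spiking = flags[["tibial_spiking"]],
               impression_oa = flags[["impression_oa"]],
               source = "coded",
               report_text = report_text_from_flags(flags),
               stringsAsFactors = FALSE)
  })
  cohort <- new_cohort(
    data.frame(patient_id = ids,
               sex = rep_len(c("female", "male"), n_total),
               birth_year = 1945L,
               registration_start = as.Date("1998-01-01"),
               registration_end = as.Date("2016-12-31"),
               stringsAsFactors = FALSE),
    do.call(rbind, ev),
    do.call(rbind, im),
    data.frame(patient_id = ids, pain_over_6_weeks = TRUE,
               gp_cause_of_pain = ifelse(gold_pos, "osteoarthritis", "other"),
               stringsAsFactors = FALSE)
  )
  list(cohort = cohort, algorithm = algorithm,
       expected = structure(list(tp = as.integer(n_tp),
                                 fp = as.integer(n_satisfying - n_tp),
                                 fn = as.integer(n_gold_positive - n_tp),
                                 tn = as.integer(n_total - n_satisfying -
                                                   (n_gold_positive - n_tp))),
                            class = "oa_twobytwo"))
}

#' Deterministic attrition fixture (93 returned questionnaires)
#'
#' Builds the 93-subject cohort matching the published attrition: with
#' injection on, [apply_exclusions()] removes 4 patients for gout, 2 for
#' rheumatoid arthritis, 1 for a total knee replacement before the index
#' code, and 1 for insufficient gold-standard data, leaving 85. With
#' `inject = FALSE` the same 93 patients carry none of the exclusion
#' conditions and all are retained. 57 of the 85 retained patients are
#' gold-standard positive.
#'
#' @param inject inject the exclusion conditions (default `TRUE`).
#' @param codesets an `oa_codesets` configuration.
#' @return an `oa_cohort` of 93 patients.
#' @export
build_exclusion_fixture <- function(inject = TRUE,
                                    codesets = default_codesets()) {
  n <- 93L
  ids <- sprintf("X%03d", seq_len(n))
  idx <- as.Date("2005-03-01")
  pain_code <- codesets$knee_pain[1]
  # the last 8 patients carry the exclusion conditions
  special <- stats::setNames(rep("none", n), ids)
  special[86:89] <- "gout"
  special[90:91] <- "ra"
  special[92] <- "tkr"
  special[93] <- "insufficient"
  gold_pos <- c(rep(TRUE, 57L), rep(FALSE, 28L), rep(FALSE, 8L))

  ev <- list(); im <- list(); qn <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    ev[[length(ev) + 1L]] <- data.frame(
      patient_id = id, code = pain_code, event_date = idx,
      stringsAsFactors = FALSE)
    sp <- special[[id]]
    if (inject && sp == "gout") {
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = id, code = codesets$exclusion_gout[1],
        event_date = idx + c(10, 24), stringsAsFactors = FALSE)
    }
    if (inject && sp == "ra") {
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = id, code = codesets$exclusion_ra[1],
        event_date = idx + c(15, 40), stringsAsFactors = FALSE)
    }
    if (inject && sp == "tkr") {
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = id, code = codesets$tkr[1],
        event_date = idx - 100, stringsAsFactors = FALSE)
    }
    insufficient <- inject && sp == "insufficient"
    if (!insufficient) {
      flags <- if (gold_pos[i]) {
        c(definite_osteophytes = TRUE, joint_space_narrowing = FALSE,
          sclerosis = FALSE, tibial_spiking = FALSE, impression_oa = TRUE)
      } else {
        c(definite_osteophytes = FALSE, joint_space_narrowing = FALSE,
          sclerosis = TRUE, tibial_spiking = FALSE, impression_oa = FALSE)
      }
      im[[length(im) + 1L]] <- data.frame(
        patient_id = id, report_date = idx, modality = "xray",
        definite_osteophytes = flags[["definite_osteophytes"]],
        joint_space_narrowing = flags[["joint_space_narrowing"]],
        sclerosis = flags[["sclerosis"]],
        tibial_spiking = flags[["tibial_spiking"]],
        impression_oa = flags[["impression_oa"]],
        source = "coded", report_text = report_text_from_flags(flags),
        stringsAsFactors = FALSE)
    }
    qn[[length(qn) + 1L]] <- data.frame(
      patient_id = id,
      pain_over_6_weeks = if (insufficient) NA else TRUE,
      gp_cause_of_pain = if (insufficient) NA_character_
                         else if (gold_pos[i]) "osteoarthritis" else "other",
      stringsAsFactors = FALSE)
  }

  new_cohort(
    data.frame(patient_id = ids,
               sex = rep_len(c("female", "male"), n),
               birth_year = 1945L,
               registration_start = as.Date("1998-01-01"),
               registration_end = as.Date("2016-12-31"),
               stringsAsFactors = FALSE),
    do.call(rbind, ev), do.call(rbind, im), do.call(rbind, qn)
  )
}
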