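test_that("empty-but-headered files read as an empty cohort", {
  d <- withr::local_tempdir()
  writeLines("patient_id,sex,birth_year,registration_start,registration_end",
             file.path(d, "patients.csv"))
  writeLines("patient_id,code,event_date", file.path(d, "events.csv"))
  writeLines(paste0("patient_id,report_date,modality,definite_osteophytes,",
                    "joint_space_narrowing,sclerosis,tibial_spiking,",
                    "impression_oa"),
             file.path(d, "imaging.csv"))
  writeLines("patient_id,pain_over_6_weeks,gp_cause_of_pain",
             file.path(d, "questionnaire.csv"))
  co <- read_cohort_dir(d)
  expect_s3_class(co, "oa_cohort")
  expect_identical(nrow(co$patients), 0L)
  expect_identical(nrow(co$events), 0L)
})

test_that("generator output round-trips through write/read unchanged", {
  co <- generate_cohort(generator_params(10, seed = 1))
  attr(co, "latent") <- NULL
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort_dir(d)
  expect_equal(back, co, ignore_attr = FALSE)
  # second round trip is byte-identical modulo nothing
  d2 <- withr::local_tempdir()
  write_cohort(back, d2)
  for (f in c("patients.csv", "events.csv", "imaging.csv",
              "questionnaire.csv")) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d, f)))
  }
})

test_that("referential integrity: orphan patient ids are rejected", {
  co <- generate_cohort(generator_params(3, seed = 2))
  attr(co, "latent") <- NULL
  d <- withr::local_tempdir()
  write_cohort(co, d)
  cat("P99,1M10.00,2005-01-01\n", file = file.path(d, "events.csv"),
      append = TRUE)
  expect_error(read_cohort_dir(d), "P99")
})

test_that("unparseable dates are reported with file, row and column", {
  co <- generate_cohort(generator_params(2, seed = 4))
  attr(co, "latent") <- NULL
  d <- withr::local_tempdir()
  write_cohort(co, d)
  ev <- utils::read.csv(file.path(d, "events.csv"),
                        colClasses = "character")
  ev$event_date[2] <- "not-a-date"
  utils::write.csv(ev, file.path(d, "events.csv"), row.names = FALSE)
  expect_error(read_cohort_dir(d), "row 2.*event_date|event_date.*row 2")
})

test_that("categorize_code resolves the published pain codes", {
  cs <- default_codesets()
  expect_identical(categorize_code("1M10.00", cs), "knee_pain")
  expect_identical(categorize_code("N094M00", cs), "knee_pain")
  expect_identical(categorize_code(c("1M12.00", "N094W00", "N094611"), cs),
                   rep("knee_pain", 3))
  expect_true(is.na(categorize_code("ZZZZZ", cs)))
})

test_that("overlapping knee_oa/knee_pain code sets fail at load", {
  cs <- unclass(default_codesets())
  cs$knee_oa <- c(cs$knee_oa, "1M10.00")
  expect_error(validate_codesets(cs), "both knee_oa and knee_pain")
})

test_that("codesets round-trip through YAML", {
  cs <- default_codesets()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_codesets(cs, p)
  expect_equal(read_codesets(p), cs)
})

test_that("cohort invariants are enforced", {
  p <- data.frame(patient_id = "A", sex = "female", birth_year = 2050L,
                  registration_start = as.Date("2000-01-01"),
                  registration_end = as.Date("2010-01-01"))
  expect_error(new_cohort(p), "birth_year")
  p$birth_year <- 1950L
  p$registration_end <- as.Date("1999-01-01")
  expect_error(new_cohort(p), "registration_start after")
})
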