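test_that("an empty cohort round-trips through header-only files", {
  d <- withr::local_tempdir()
  write_cohort(ehr_cohort(), d)
  expect_true(all(file.exists(file.path(d, paste0(
    c("admissions", "labs", "cultures", "flowsheets", "medications",
      "procedures"), ".csv")))))
  co <- read_cohort(d)
  expect_s3_class(co, "ehr_cohort")
  expect_identical(nrow(co$admissions), 0L)
  expect_identical(nrow(co$labs), 0L)
})

test_that("a generated cohort survives a write/read round trip", {
  gen <- generate_cohort(synth_config(n_admissions = 40, seed = 11))
  d <- withr::local_tempdir()
  write_cohort(gen$cohort, d)
  back <- read_cohort(d)
  for (tab in c("admissions", "labs", "cultures", "flowsheets",
                "medications", "procedures")) {
    expect_equal(back[[tab]], gen$cohort[[tab]], info = tab)
  }
  expect_identical(nrow(validate_cohort(back)), 0L)
})

test_that("a hand-written fixture file parses field by field", {
  d <- withr::local_tempdir()
  write_cohort(ehr_cohort(), d)  # header-only files for the other tables
  writeLines(c(
    "encounter_id,patient_id,admit_time,discharge_time,died_inpatient,raw_financial_class,sex,race_ethnicity,age_years,billed_icd_codes,billed_drg_code",
    "e9,p9,2019-03-01T08:00:00Z,2019-03-04T12:30:00Z,FALSE,Medicare,male,Black,71,e87.1; I10,102"),
    file.path(d, "admissions.csv"))
  writeLines(c(
    "encounter_id,patient_id,collected_time,analyte,numeric_value,abnormal_flag",
    "e9,p9,2019-03-02T06:00:00Z,arterial_pH,7.31,abnormal"),
    file.path(d, "labs.csv"))
  co <- read_cohort(d)
  a <- co$admissions
  expect_identical(a$encounter_id, "e9")
  expect_identical(a$sex, "male")
  expect_identical(a$age_years, 71)
  # ICD list normalized: uppercase, whitespace stripped, deduplicated
  expect_identical(a$billed_icd_codes, "E87.1;I10")
  expect_s3_class(a$admit_time, "POSIXct")
  expect_equal(as.numeric(difftime(a$discharge_time, a$admit_time,
                                   units = "days")), 3.1875)
  expect_identical(co$labs$encounter_id, "e9")
  expect_identical(co$labs$numeric_value, 7.31)
  expect_identical(nrow(validate_cohort(co)), 0L)
})

test_that("schema errors are fatal and name the file and column", {
  d <- withr::local_tempdir()
  expect_error(read_cohort(d), "admissions\\.csv")
  write_cohort(ehr_cohort(), d)
  labs <- utils::read.csv(file.path(d, "labs.csv"))
  utils::write.csv(labs[setdiff(names(labs), "analyte")],
                   file.path(d, "labs.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "labs.*analyte")
})

test_that("unknown columns are dropped with a warning", {
  d <- withr::local_tempdir()
  write_cohort(one_adm_cohort(), d)
  adm <- utils::read.csv(file.path(d, "admissions.csv"))
  adm$mrn <- "123"
  utils::write.csv(adm, file.path(d, "admissions.csv"), row.names = FALSE)
  expect_warning(co <- read_cohort(d), "mrn")
  expect_false("mrn" %in% names(co$admissions))
})

test_that("an unparseable timestamp is reported with its row index", {
  d <- withr::local_tempdir()
  write_cohort(one_adm_cohort(lab_row(101, "sodium", 130)), d)
  labs <- utils::read.csv(file.path(d, "labs.csv"),
                          colClasses = "character")
  labs$collected_time <- "not-a-time"
  utils::write.csv(labs, file.path(d, "labs.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "row\\(s\\) 1")
})

test_that("validate_cohort reports each invariant violation with a locator", {
  expect_identical(nrow(validate_cohort(
    generate_cohort(synth_config(n_admissions = 60, seed = 3))$cohort)), 0L)

  dangling <- one_adm_cohort(lab_row(101, "sodium", 130, enc = "ghost",
                                     pat = "nobody"))
  v <- validate_cohort(dangling)
  expect_identical(v$rule, "dangling_reference")
  expect_identical(v$table, "labs")

  backwards <- ehr_cohort(adm_row(admit = 105, discharge = 100))
  v <- validate_cohort(backwards)
  expect_identical(v$rule, "time_ordering")

  bad_gcs <- one_adm_cohort(flow_row(101, "GCS_total", 17))
  expect_identical(validate_cohort(bad_gcs)$rule, "GCS_total_range")

  no_value <- one_adm_cohort(lab_row(101, "sodium"))
  expect_identical(validate_cohort(no_value)$rule, "value_or_flag")

  blood_colony <- one_adm_cohort(culture_row(101, "blood", TRUE, colony = 10))
  expect_identical(validate_cohort(blood_colony)$rule, "colony_urine_only")
})

test_that("deidentify hashes ids and re-bases times on each patient's first event", {
  co <- ehr_cohort(
    admissions = adm_row("e1", "p1", admit = 1000, discharge = 1003),
    labs = rbind(lab_row(1000, "sodium", 130),
                 lab_row(1003, "sodium", 131)))
  de <- deidentify(co, "salt-a")
  expect_identical(de$admissions$admit_time, 0)
  expect_identical(de$labs$collected_time, c(0, 3))
  expect_false(de$admissions$encounter_id == "e1")
  expect_false(de$admissions$patient_id == "p1")
  # join preserved: lab still resolves to the (hashed) admission
  expect_identical(unique(de$labs$encounter_id), de$admissions$encounter_id)
})

test_that("different salts give disjoint ids but identical offsets", {
  gen <- generate_cohort(synth_config(n_admissions = 25, seed = 5))
  d1 <- deidentify(gen$cohort, "salt-one")
  d2 <- deidentify(gen$cohort, "salt-two")
  expect_length(intersect(d1$admissions$encounter_id,
                          d2$admissions$encounter_id), 0)
  expect_length(intersect(d1$admissions$patient_id,
                          d2$admissions$patient_id), 0)
  for (tab in c("admissions", "labs", "flowsheets")) {
    tcols <- intersect(c("admit_time", "discharge_time", "collected_time",
                         "observed_time"), names(d1[[tab]]))
    for (cl in tcols) expect_identical(d1[[tab]][[cl]], d2[[tab]][[cl]])
  }
  # validation results unchanged by de-identification
  expect_identical(nrow(validate_cohort(d1)),
                   nrow(validate_cohort(gen$cohort)))
})

test_that("deidentify preserves pairwise intervals and link counts", {
  gen <- generate_cohort(synth_config(n_admissions = 25, seed = 6))
  de <- deidentify(gen$cohort, "s")
  # within-patient inter-event intervals are preserved exactly (each
  # patient's clock is re-based independently)
  gaps <- function(co) {
    t <- co$labs$collected_time
    t <- if (inherits(t, "POSIXct")) as.numeric(t) / 86400 else t
    g <- unlist(lapply(split(t, co$labs$patient_id),
                       function(v) diff(sort(v))))
    sort(unname(g))
  }
  expect_equal(gaps(de), gaps(gen$cohort), tolerance = 1e-9)
  n_linked <- function(co) as.vector(table(factor(
    co$labs$encounter_id[!is.na(co$labs$encounter_id)])))
  expect_identical(sort(n_linked(de)), sort(n_linked(gen$cohort)))
  expect_error(deidentify(gen$cohort, ""), "salt")
})

test_that("single-event patients get offset zero", {
  co <- ehr_cohort(admissions = adm_row(admit = 500, discharge = 500))
  de <- deidentify(co, "x")
  expect_identical(de$admissions$admit_time, 0)
  expect_identical(de$admissions$discharge_time, 0)
})
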