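rb <- build_rulebook()

test_that("the rulebook carries nineteen algorithms with the stated levels", {
  expect_length(rb, 19)
  levels <- vapply(rb, `[[`, character(1), "modifier_level")
  expect_identical(sum(levels == "CC"), 12L)
  expect_identical(sum(levels == "MCC"), 7L)
  expect_identical(rb[["Acute Pancreatitis"]]$modifier_level, "MCC")
  expect_identical(rb[["Hyponatremia"]]$qualifying_icd_patterns, "E87.1")
  expect_length(rb[["Inpatient Death"]]$qualifying_icd_patterns, 0)
  expect_false(anyDuplicated(names(rb)) > 0)
})

test_that("MDRD eGFR matches the four-variable closed form", {
  # independent in-test evaluation of 175 * Scr^-1.154 * age^-0.203 * factors
  expected <- 175 * 2.5^(-1.154) * 60^(-0.203) * 0.742
  expect_equal(egfr_mdrd(2.5, 60, "female", FALSE), expected)
  expect_equal(round(expected, 1), 19.6)  # CKD-positive territory (<= 30)
  expect_equal(egfr_mdrd(1.0, 50, "female", FALSE),
               0.742 * egfr_mdrd(1.0, 50, "male", FALSE))
  expect_equal(egfr_mdrd(1.0, 50, "male", TRUE),
               1.212 * egfr_mdrd(1.0, 50, "male", FALSE))
  # formula is total on positive reals, even outside the adult range
  expect_gt(egfr_mdrd(1.0, 1, "male", FALSE), 0)
  expect_error(egfr_mdrd(0, 60, "male", FALSE), "positive")
  expect_error(egfr_mdrd(1, -3, "male", FALSE), "positive")
})

test_that("within_window has inclusive boundaries in both directions", {
  ev <- data.frame(event_time = c(-400, -365, -10, 0, 1, 365, 366))
  before <- within_window(ev, 0, 365, "before")
  expect_identical(before$event_time, c(-365, -10, 0))
  after <- within_window(ev, 0, 365, "after")
  expect_identical(after$event_time, c(0, 1, 365))
  expect_identical(within_window(ev, 0, 30, "before")$event_time, c(-10, 0))
})

test_that("evaluate_rule matches the documented per-rule behaviour", {
  expect_true(detect1(rb, "Acidemia",
                      one_adm_cohort(lab_row(101, "arterial_pH", 7.30))))
  expect_false(detect1(rb, "Acidemia",
                       one_adm_cohort(lab_row(101, "arterial_pH", 7.35))))
  # missing numeric value never satisfies a thresholded rule
  expect_false(detect1(rb, "Acidemia",
                       one_adm_cohort(lab_row(101, "arterial_pH",
                                              flag = "abnormal"))))
  expect_false(detect1(rb, "Bacteremia",
                       one_adm_cohort(culture_row(101, "blood", TRUE))))
  expect_true(detect1(rb, "Bacteremia",
                      one_adm_cohort(culture_row(101, "blood", TRUE),
                                     culture_row(102, "blood", TRUE))))
  # airway support is overridden by any surgery during the index admission
  expect_true(detect1(rb, "Respiratory Failure",
                      one_adm_cohort(flow_row(101, "airway_device",
                                              vchr = "HFNC"))))
  expect_false(detect1(rb, "Respiratory Failure",
                       one_adm_cohort(flow_row(101, "airway_device",
                                               vchr = "HFNC"),
                                      proc_row(102, "surgery_case"))))
  # post-op anemia window: hemoglobin at +23h counts, at +25h does not
  postop <- function(hgb_offset_h) one_adm_cohort(
    proc_row(101, "surgery_case"),
    flow_row(101, "intraop_blood_loss_mL", 300),
    lab_row(101 + hgb_offset_h / 24, "hemoglobin", 11.9))
  expect_true(detect1(rb, "Blood Loss Anemia", postop(23)))
  expect_false(detect1(rb, "Blood Loss Anemia", postop(25)))
})

test_that("lookback rules see patient-level history and index results", {
  hist_ef <- ehr_cohort(
    admissions = adm_row(),
    flowsheets = flow_row(100 - 200, "ejection_fraction", 25,
                          enc = NA_character_))
  expect_true(detect1(rb, "Chronic CHF", hist_ef))
  # exactly 365 days before admission is still inside the window
  at_edge <- ehr_cohort(
    admissions = adm_row(),
    flowsheets = flow_row(100 - 365, "ejection_fraction", 25,
                          enc = NA_character_))
  expect_true(detect1(rb, "Chronic CHF", at_edge))
  past_edge <- ehr_cohort(
    admissions = adm_row(),
    flowsheets = flow_row(100 - 365.5, "ejection_fraction", 25,
                          enc = NA_character_))
  expect_false(detect1(rb, "Chronic CHF", past_edge))
  # an intra-admission BNP also counts toward chronic CHF
  intra_bnp <- one_adm_cohort(lab_row(102, "BNP", 1200))
  expect_true(detect1(rb, "Chronic CHF", intra_bnp))
})

test_that("an admission with no clinical records and an inpatient death flags only the death rule", {
  co <- ehr_cohort(admissions = adm_row(died = TRUE))
  calls <- evaluate_cohort(rb, co)
  expect_identical(nrow(calls), 19L)
  expect_identical(calls$disease_name[calls$detected], "Inpatient Death")
})

test_that("evaluation is empty on an empty cohort and invariant to record order", {
  expect_identical(nrow(evaluate_cohort(rb, ehr_cohort())), 0L)
  gen <- generate_cohort(synth_config(n_admissions = 30, seed = 9))
  base <- evaluate_cohort(rb, gen$cohort)
  shuffled <- gen$cohort
  set.seed(1)
  for (tab in c("labs", "cultures", "flowsheets", "medications",
                "procedures")) {
    df <- shuffled[[tab]]
    if (nrow(df) > 1) {
      shuffled[[tab]] <- df[sample(nrow(df)), , drop = FALSE]
      rownames(shuffled[[tab]]) <- NULL
    }
  }
  again <- evaluate_cohort(rb, shuffled)
  cols <- c("encounter_id", "disease_name", "detected", "n_evidence")
  expect_identical(base[cols], again[cols])
})

test_that("detection is monotone in added records, inverted for the surgery exclusion", {
  gen <- generate_cohort(synth_config(n_admissions = 15, seed = 13))
  co <- gen$cohort
  before <- evaluate_cohort(rb, co)
  target <- co$admissions$encounter_id[1]
  target_pat <- co$admissions$patient_id[1]
  t_mid <- co$admissions$admit_time[1] + 3600
  co$labs <- rbind(co$labs,
                   lab_row(t_mid, "sodium", 120, enc = target,
                           pat = target_pat))
  after <- evaluate_cohort(rb, co)
  flipped <- before$detected != after$detected
  expect_true(all(before$disease_name[flipped] == "Hyponatremia"))
  expect_true(all(after$detected[flipped]))  # only false -> true

  # adding a surgery can only turn Respiratory Failure off, never on
  co2 <- gen$cohort
  co2$procedures <- rbind(
    co2$procedures,
    proc_row(co2$admissions$admit_time + 3600, "surgery_case",
             enc = co2$admissions$encounter_id,
             pat = co2$admissions$patient_id))
  after2 <- evaluate_cohort(rb, co2)
  rf_b <- before$detected[before$disease_name == "Respiratory Failure"]
  rf_a <- after2$detected[after2$disease_name == "Respiratory Failure"]
  expect_true(all(rf_a <= rf_b))
  other <- before$disease_name != "Respiratory Failure"
  expect_identical(before$detected[other], after2$detected[other])
})

test_that("threshold overrides rebuild a retuned rulebook", {
  rb2 <- build_rulebook(list(sodium_max = 130))
  co <- one_adm_cohort(lab_row(101, "sodium", 132))
  expect_true(detect1(rb, "Hyponatremia", co))
  expect_false(detect1(rb2, "Hyponatremia", co))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(gcs_max = 6), yml)
  rb3 <- build_rulebook(yml)
  co2 <- one_adm_cohort(flow_row(101, "GCS_total", 7))
  expect_true(detect1(rb, "Altered Mental Status", co2))
  expect_false(detect1(rb3, "Altered Mental Status", co2))
})
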