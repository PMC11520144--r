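# In-code fixtures. Timestamps are plain numeric day offsets (the cohort
# model accepts either POSIXct or numeric days), which keeps window
# arithmetic in the tests exact and legible.

adm_row <- function(enc = "e1", pat = "p1", admit = 100, discharge = 105,
                    died = FALSE, fc = "Blue Cross PPO", sex = "female",
                    race = "Caucasian-Non-Hispanic", age = 60, icd = "",
                    drg = NA_character_) {
  data.frame(encounter_id = enc, patient_id = pat, admit_time = admit,
             discharge_time = discharge, died_inpatient = died,
             raw_financial_class = fc, sex = sex, race_ethnicity = race,
             age_years = age, billed_icd_codes = icd, billed_drg_code = drg,
             stringsAsFactors = FALSE)
}

lab_row <- function(t, analyte, value = NA_real_, flag = NA_character_,
                    enc = "e1", pat = "p1") {
  data.frame(encounter_id = enc, patient_id = pat, collected_time = t,
             analyte = analyte, numeric_value = value, abnormal_flag = flag,
             stringsAsFactors = FALSE)
}

culture_row <- function(t, specimen, positive, colony = NA_real_,
                        enc = "e1") {
  data.frame(encounter_id = enc, collected_time = t, specimen = specimen,
             positive = positive, colony_count = colony,
             stringsAsFactors = FALSE)
}

flow_row <- function(t, measure, vnum = NA_real_, vchr = NA_character_,
                     enc = "e1", pat = "p1") {
  data.frame(encounter_id = enc, patient_id = pat, observed_time = t,
             measure = measure, value_num = vnum, value_chr = vchr,
             stringsAsFactors = FALSE)
}

med_row <- function(t, drug, kind = "administration", enc = "e1",
                    pat = "p1") {
  data.frame(encounter_id = enc, patient_id = pat, event_time = t,
             drug = drug, event_kind = kind, stringsAsFactors = FALSE)
}

proc_row <- function(t, kind, cpt = NA_character_, enc = "e1", pat = "p1") {
  data.frame(encounter_id = enc, patient_id = pat, event_time = t,
             kind = kind, cpt_codes = cpt, stringsAsFactors = FALSE)
}

# single-admission cohort with arbitrary clinical records
one_adm_cohort <- function(..., adm = adm_row()) {
  recs <- list(...)
  pick <- function(col) {
    hits <- Filter(function(d) col %in% names(d), recs)
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  ehr_cohort(admissions = adm,
             labs = pick("analyte"),
             cultures = pick("colony_count"),
             flowsheets = pick("measure"),
             medications = pick("drug"),
             procedures = pick("cpt_codes"))
}

# evaluate one rule on a one-admission cohort and return detected
detect1 <- function(rulebook, disease, cohort, enc = "e1") {
  evaluate_rule(rulebook[[disease]], enc, cohort)$detected
}

# a deterministic hand-built three-admission cohort used across tests
mini_cohort <- function() {
  adm <- rbind(
    adm_row("e1", "p1", 100, 105, icd = "E87.1;I10", drg = "102",
            fc = "Medicare"),
    adm_row("e2", "p2", 200, 203, died = TRUE, drg = "103",
            fc = "Medicaid", icd = "K85.90"),
    adm_row("e3", "p3", 300, 310, drg = "231", fc = "Aetna HMO"))
  ehr_cohort(
    admissions = adm,
    labs = rbind(lab_row(101, "sodium", 130),
                 lab_row(102.5, "arterial_pH", 7.40, "normal"),
                 lab_row(301, "amylase", 1500, enc = "e3", pat = "p3")),
    flowsheets = flow_row(201, "GCS_total", 6, enc = "e2", pat = "p2"))
}

mini_catalogue <- function() {
  load_drg_catalogue(data.frame(
    drg_code = c("101", "102", "103", "231"),
    description = c("PLEURAL EFFUSION WITH MCC", "PLEURAL EFFUSION WITH CC",
                    "PLEURAL EFFUSION WITHOUT CC/MCC", "HEART TRANSPLANT"),
    rwf = c(1.6215, 1.1872, 0.8811, 7.9431), stringsAsFactors = FALSE))
}
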