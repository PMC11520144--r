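rb <- build_rulebook()

test_that("ICD wildcard semantics: literal exact, wildcard root-and-children", {
  expect_true(match_icd("I50.*", "I50.9"))
  expect_true(match_icd("I50.*", "I50"))
  expect_false(match_icd("I50.*", "I509"))
  expect_false(match_icd("I50.*", "I51.9"))
  expect_false(match_icd("E87.1", "E87.11"))
  expect_true(match_icd("E87.1", "e87.1 "))  # normalization
  expect_true(match_icd("K85.*", "K85"))
  expect_false(match_icd("K85.*", "K851"))
  expect_true(match_icd("K85*", "K85.90"))
  # children-only mode excludes the bare root
  expect_false(match_icd("K85.*", "K85", include_root = FALSE))
  expect_true(match_icd("K85.*", "K85.0", include_root = FALSE))
  expect_error(match_icd("", "K85"), "non-empty")
  expect_error(match_icd("K*5.*", "K85"), "malformed")
  # malformed patterns fail at rulebook construction, not at match time
  expect_error(drgaudit:::new_rule("X", "CC", "A*B", function(cohort) NULL),
               "malformed")
})

test_that("omission flags combine detection with qualifying-code presence", {
  rule <- rb[["Hyponatremia"]]
  call <- list(encounter_id = "e1", disease_name = "Hyponatremia",
               detected = TRUE)
  f <- flag_missing_icd(call, adm_row(icd = "E87.1;I10"), rule)
  expect_false(f$missing_icd); expect_true(f$icd_present)
  f <- flag_missing_icd(call, adm_row(icd = ""), rule)
  expect_true(f$missing_icd); expect_false(f$icd_present)
  # code present without clinical evidence: the not-sensitive cell
  call$detected <- FALSE
  f <- flag_missing_icd(list(encounter_id = "e1",
                             disease_name = "Acute Pancreatitis",
                             detected = FALSE),
                        adm_row(icd = "K85.90"), rb[["Acute Pancreatitis"]])
  expect_false(f$missing_icd); expect_true(f$icd_present)
  # death has no qualifying list and is never flagged missing
  f <- flag_missing_icd(list(encounter_id = "e1",
                             disease_name = "Inpatient Death",
                             detected = TRUE),
                        adm_row(icd = ""), rb[["Inpatient Death"]])
  expect_false(f$missing_icd)
})

test_that("DRG descriptions classify by severity suffix, case-insensitively", {
  expect_identical(classify_drg("PLEURAL EFFUSION WITH MCC"), "MCC")
  expect_identical(classify_drg("Pleural Effusion with CC"), "CC")
  expect_identical(classify_drg("PLEURAL EFFUSION WITHOUT CC/MCC"), "BASE")
  expect_identical(classify_drg("X WITHOUT MCC"), "BASE")
  expect_identical(classify_drg("X WITHOUT CC"), "BASE")
  expect_identical(classify_drg("X WITH CC/MCC"), "CC/MCC")
  expect_identical(classify_drg("HEART TRANSPLANT"), "SINGLET")
  # suffix must be terminal
  expect_identical(classify_drg("WITH MCC PROCEDURES"), "SINGLET")
})

test_that("strip_family removes recognized suffixes and is idempotent", {
  suffixes <- c(" WITH MCC", " WITH CC", " WITH CC/MCC",
                " WITHOUT CC/MCC", " WITHOUT MCC", " WITHOUT CC", "")
  for (s in suffixes) {
    out <- strip_family(paste0("PLEURAL EFFUSION", s))
    expect_identical(out, "PLEURAL EFFUSION", label = paste0("suffix '", s, "'"))
    expect_identical(strip_family(out), out)
  }
})

test_that("catalogue loading levels and families every entry", {
  cat3 <- mini_catalogue()
  expect_identical(nrow(cat3), 4L)
  pe <- cat3[cat3$family == "PLEURAL EFFUSION", ]
  expect_setequal(pe$level, c("BASE", "CC", "MCC"))
  expect_identical(cat3$level[cat3$description == "HEART TRANSPLANT"],
                   "SINGLET")
  # the family pass turns a bare description with leveled siblings into BASE
  cat2 <- load_drg_catalogue(data.frame(
    drg_code = c("1", "2"), description = c("CELLULITIS WITH MCC",
                                            "CELLULITIS"),
    rwf = c(1.5, 0.9)))
  expect_identical(cat2$level[cat2$drg_code == "2"], "BASE")
  expect_identical(nrow(load_drg_catalogue(
    data.frame(drg_code = character(0), description = character(0),
               rwf = numeric(0)))), 0L)
  expect_error(load_drg_catalogue(data.frame(
    drg_code = c("1", "1"), description = c("A", "B"), rwf = c(1, 2))),
    "duplicate")
  expect_error(load_drg_catalogue(data.frame(
    drg_code = "1", description = "A", rwf = NA)), "missing rwf")
})

test_that("upgrade evaluation picks the family entry at the required level", {
  cat3 <- mini_catalogue()
  entry <- function(code) cat3[cat3$drg_code == code, ]
  det_mcc <- data.frame(disease_name = "Acute Pancreatitis",
                        modifier_level = "MCC")
  det_cc <- data.frame(disease_name = "Hyponatremia", modifier_level = "CC")

  up <- evaluate_upgrade(det_mcc, entry("102"), cat3)
  expect_identical(up$upgrade_type, "CC_to_MCC")
  expect_identical(up$target_drg, "101")
  expect_equal(up$delta_rwf, 1.6215 - 1.1872)

  expect_identical(evaluate_upgrade(det_cc, entry("101"), cat3)$upgrade_type,
                   "none")
  both <- rbind(det_cc, det_mcc)
  up <- evaluate_upgrade(both, entry("103"), cat3)
  expect_identical(up$upgrade_type, "base_to_MCC")
  expect_identical(up$driving_diseases, "Acute Pancreatitis;Hyponatremia")
  # a Singlet billed DRG is never modified
  expect_identical(evaluate_upgrade(both, entry("231"), cat3)$upgrade_type,
                   "none")
  expect_identical(evaluate_upgrade(both[0, ], entry("103"), cat3)$upgrade_type,
                   "none")
  expect_gte(up$delta_rwf, 0)
})

test_that("a doublet family falls back to its CC/MCC arm for MCC upgrades", {
  dbl <- load_drg_catalogue(data.frame(
    drg_code = c("221", "222"),
    description = c("RED BLOOD CELL DISORDERS WITH CC/MCC",
                    "RED BLOOD CELL DISORDERS WITHOUT CC/MCC"),
    rwf = c(1.1921, 0.8308)))
  det_mcc <- data.frame(disease_name = "Severe Malnutrition",
                        modifier_level = "MCC")
  det_cc <- data.frame(disease_name = "UTI", modifier_level = "CC")
  billed <- dbl[dbl$drg_code == "222", ]
  up <- evaluate_upgrade(det_mcc, billed, dbl)
  expect_identical(up$upgrade_type, "base_to_MCC")
  expect_identical(up$target_drg, "221")
  # the CC/MCC arm satisfies CC when billed: no upgrade for a CC disease
  expect_identical(
    evaluate_upgrade(det_cc, dbl[dbl$drg_code == "221", ], dbl)$upgrade_type,
    "none")
  # a CC-only requirement cannot target the doublet arm (MCC-satisfying)
  expect_identical(evaluate_upgrade(det_cc, billed, dbl)$upgrade_type,
                   "none")
})

test_that("cohort-level upgrades skip and report uncatalogued billed DRGs", {
  co <- mini_cohort()
  calls <- evaluate_cohort(rb, co)
  cat3 <- mini_catalogue()
  co$admissions$billed_drg_code[2] <- "999"
  expect_warning(ups <- evaluate_upgrades(calls, co, cat3), "excluded")
  expect_identical(nrow(ups), 2L)
  expect_false("e2" %in% ups$encounter_id)
})

test_that("per-disease accounting identity holds and findings are idempotent", {
  gen <- generate_cohort(synth_config(n_admissions = 120, seed = 21))
  calls <- evaluate_cohort(rb, gen$cohort)
  f1 <- audit_findings(calls, gen$cohort, rb)
  f2 <- audit_findings(calls, gen$cohort, rb)
  expect_identical(f1, f2)
  for (d in setdiff(unique(f1$disease_name), "Inpatient Death")) {
    f <- f1[f1$disease_name == d, ]
    expect_identical(sum(f$detected & f$icd_present) + sum(f$missing_icd),
                     sum(f$detected), label = d)
  }
})
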