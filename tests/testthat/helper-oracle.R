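# Naive reference implementations, written independently of the package
# internals: a per-admission brute-force phenotype evaluator that re-scans
# every record table with plain subsetting, a regex ICD matcher, and an
# exhaustive upgrade-target search. Used as oracles for equivalence tests.

.days <- function(x) if (inherits(x, "POSIXct")) as.numeric(x) / 86400 else as.numeric(x)

naive_evaluate_admission <- function(a, co) {
  admit <- .days(a$admit_time); dis <- .days(a$discharge_time)
  labs <- co$labs; cul <- co$cultures; fs <- co$flowsheets
  med <- co$medications; pr <- co$procedures
  in_enc <- function(df, tcol) {
    t <- .days(df[[tcol]])
    df[!is.na(df$encounter_id) & df$encounter_id == a$encounter_id &
         !is.na(t) & t >= admit & t <= dis, , drop = FALSE]
  }
  by_pat <- function(df, tcol, from, to) {
    t <- .days(df[[tcol]])
    p <- df$patient_id
    if (is.null(p)) return(df[0, , drop = FALSE])
    df[!is.na(p) & p == a$patient_id & !is.na(t) & t >= from & t <= to, ,
       drop = FALSE]
  }
  el <- in_enc(labs, "collected_time")
  ec <- in_enc(cul, "collected_time")
  ef <- in_enc(fs, "observed_time")
  em <- in_enc(med, "event_time")
  ep <- in_enc(pr, "event_time")
  num_ok <- function(df, col = "numeric_value") !is.na(df[[col]])
  lk_fs <- by_pat(fs, "observed_time", admit - 365, dis)
  lk_lab <- by_pat(labs, "collected_time", admit - 365, dis)

  trop_pos <- any(el$analyte == "troponin" & !is.na(el$abnormal_flag) &
                    el$abnormal_flag == "positive")
  has_surgery <- any(ep$kind == "surgery_case")

  bl_anemia <- FALSE
  ebl <- ef[ef$measure == "intraop_blood_loss_mL" & num_ok(ef, "value_num") &
              ef$value_num >= 300, , drop = FALSE]
  hgb <- el[el$analyte == "hemoglobin" & num_ok(el) & el$numeric_value < 12, ,
            drop = FALSE]
  for (te in .days(ebl$observed_time)) {
    for (thg in .days(hgb$collected_time)) {
      if (thg > te && thg <= te + 1) bl_anemia <- TRUE
    }
  }

  mdrd <- function(scr) {
    175 * scr^(-1.154) * a$age_years^(-0.203) *
      (if (a$sex == "female") 0.742 else 1) *
      (if (a$race_ethnicity == "Black") 1.212 else 1)
  }
  scr <- el[el$analyte == "serum_creatinine" & num_ok(el) &
              el$numeric_value > 0, , drop = FALSE]

  hist_lab <- by_pat(labs, "collected_time", -Inf, dis)
  hist_pr <- by_pat(pr, "event_time", -Inf, dis)

  c("Acidemia" = any(el$analyte == "arterial_pH" & num_ok(el) &
                       el$numeric_value < 7.35),
    "Bacteremia" = sum(ec$specimen == "blood" & !is.na(ec$positive) &
                         ec$positive) >= 2,
    "Blood Loss Anemia" = bl_anemia,
    "Chronic CHF" = any(lk_fs$measure == "ejection_fraction" &
                          !is.na(lk_fs$value_num) & lk_fs$value_num <= 30) ||
      any(lk_lab$analyte == "BNP" & !is.na(lk_lab$numeric_value) &
            lk_lab$numeric_value > 900) ||
      any(lk_fs$measure == "problem_list_heart_failure" &
            ((!is.na(lk_fs$value_chr) &
                tolower(lk_fs$value_chr) %in% c("present", "true", "yes", "1")) |
               (!is.na(lk_fs$value_num) & lk_fs$value_num == 1))),
    "Chronic Kidney Disease" = nrow(scr) > 0 && a$age_years > 0 &&
      any(vapply(scr$numeric_value, mdrd, numeric(1)) <= 30),
    "Delirium" = any(ef$measure == "CAM_result" & !is.na(ef$value_chr) &
                       tolower(ef$value_chr) == "positive"),
    "Extremes of BMI" = any(ef$measure == "BMI" & !is.na(ef$value_num) &
                              (ef$value_num > 40 | ef$value_num < 19)),
    "HIV" = any(hist_lab$analyte == "HIV_screen" &
                  !is.na(hist_lab$abnormal_flag) &
                  hist_lab$abnormal_flag == "positive") ||
      any(tolower(em$drug) == "zidovudine" & em$event_kind == "order_active"),
    "Hyponatremia" = any(el$analyte == "sodium" & num_ok(el) &
                           el$numeric_value <= 134),
    "Myocardial Injury" = trop_pos,
    "Transplant" = any(hist_pr$kind == "transplant_surgery") ||
      any(tolower(em$drug) == "tacrolimus" &
            em$event_kind == "administration"),
    "UTI" = any(ec$specimen == "urine" & !is.na(ec$colony_count) &
                  ec$colony_count >= 1e5),
    "Acute MI" = trop_pos && any(ep$kind == "coronary_stent"),
    "Acute Pancreatitis" = any(el$analyte == "amylase" & num_ok(el) &
                                 el$numeric_value > 1000) ||
      any(el$analyte == "lipase" & num_ok(el) & el$numeric_value > 450),
    "Altered Mental Status" = any(ef$measure == "GCS_total" &
                                    !is.na(ef$value_num) & ef$value_num <= 8),
    "End Stage Renal Disease" = any(ef$measure == "dialysis_flow"),
    "Inpatient Death" = isTRUE(a$died_inpatient),
    "Respiratory Failure" = any(ef$measure == "airway_device" &
                                  !is.na(ef$value_chr) &
                                  tolower(ef$value_chr) %in%
                                    c("endotracheal_tube", "hfnc")) &&
      !has_surgery,
    "Severe Malnutrition" = any(toupper(em$drug) == "TPN"))
}

naive_evaluate <- function(co) {
  adm <- co$admissions
  out <- lapply(seq_len(nrow(adm)), function(i) {
    det <- naive_evaluate_admission(adm[i, ], co)
    data.frame(encounter_id = adm$encounter_id[i],
               disease_name = names(det), detected = unname(det),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# regex-based ICD matcher, independent of match_icd
naive_icd_match <- function(pattern, code) {
  code <- toupper(gsub(" ", "", code))
  if (grepl("\\*$", pattern)) {
    root <- sub("\\.?\\*$", "", toupper(pattern))
    grepl(paste0("^", gsub("\\.", "\\\\.", root), "($|\\.)"), code)
  } else {
    code == toupper(pattern)
  }
}

# exhaustive upgrade-target search over (entry) pairs of a catalogue whose
# family/level columns are known by construction (not via classify_drg)
naive_target <- function(billed, required_val, cat_df) {
  bval <- c(BASE = 0, CC = 1, "CC/MCC" = 1, MCC = 2)[[billed$level]]
  tval <- function(lv) c(CC = 1, "CC/MCC" = 2, MCC = 2)[[lv]]
  best <- NULL
  for (i in seq_len(nrow(cat_df))) {
    e <- cat_df[i, ]
    if (e$family != billed$family) next
    if (!(e$level %in% c("CC", "MCC", "CC/MCC"))) next
    tv <- tval(e$level)
    if (tv <= bval || tv > required_val) next
    if (is.null(best) || tv > tval(best$level) ||
        (tv == tval(best$level) && nchar(e$level) < nchar(best$level)) ||
        (tv == tval(best$level) && nchar(e$level) == nchar(best$level) &&
           e$drg_code < best$drg_code)) {
      best <- e
    }
  }
  best
}
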