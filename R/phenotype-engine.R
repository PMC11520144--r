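# Declarative disease phenotyping: nineteen rules-based algorithms evaluated
# against raw structured EHR data. Twelve rules are CC-level (comorbid
# condition) and seven MCC-level (major comorbid condition). Each rule is a
# deterministic predicate over labs, cultures, flowsheets, medication events
# and procedure logs; an admission is flagged as having or not having each
# disease, with the satisfying records retained as evidence.

#' Default clinical thresholds for the phenotype rulebook
#'
#' All tunable operands of the nineteen disease algorithms, in clinical
#' units, so sites can retune a rulebook without code changes (pass a
#' modified list -- or a YAML file of the same shape -- to
#' [build_rulebook()]). Inequality strictness is part of the rule
#' definitions, not of these values: arterial pH and BMI bounds are strict,
#' sodium/eGFR/GCS/EF bounds and the 300 mL blood-loss and 100,000 CFU/mL
#' cutoffs are inclusive.
#'
#' @return named list of thresholds:
#' \describe{
#'   \item{ph_max}{arterial pH upper bound for acidemia (strict), 7.35}
#'   \item{min_blood_cultures}{positive blood cultures required, 2}
#'   \item{ebl_min_ml}{intraoperative blood loss, mL (inclusive), 300}
#'   \item{hgb_max}{post-operative hemoglobin, g/dL (strict), 12}
#'   \item{postop_window_days}{hemoglobin window after surgery end, 1}
#'   \item{ef_max}{echocardiographic ejection fraction, \% (inclusive), 30}
#'   \item{bnp_min}{BNP, pg/mL (strict), 900}
#'   \item{lookback_days}{patient-level lookback window, days, 365}
#'   \item{egfr_max}{MDRD eGFR, mL/min/1.73m2 (inclusive), 30}
#'   \item{bmi_high,bmi_low}{BMI bounds (both strict), 40 and 19}
#'   \item{sodium_max}{serum sodium, mmol/L (inclusive), 134}
#'   \item{amylase_min}{serum amylase, U/L (strict), 1000}
#'   \item{lipase_min}{serum lipase, U/L (strict), 450}
#'   \item{gcs_max}{Glasgow Coma Scale total (inclusive), 8}
#'   \item{colony_min}{urine colony count, CFU/mL (inclusive), 1e5}
#'   \item{troponin_threshold}{optional numeric troponin cutoff; `NA` means
#'     the lab's `abnormal_flag == "positive"` is used (assay-dependent)}
#' }
#' @export
default_thresholds <- function() {
  list(ph_max = 7.35, min_blood_cultures = 2, ebl_min_ml = 300, hgb_max = 12,
       postop_window_days = 1, ef_max = 30, bnp_min = 900,
       lookback_days = 365, egfr_max = 30, bmi_high = 40, bmi_low = 19,
       sodium_max = 134, amylase_min = 1000, lipase_min = 450, gcs_max = 8,
       colony_min = 1e5, troponin_threshold = NA_real_)
}

#' Estimated glomerular filtration rate (4-variable MDRD)
#'
#' `175 * Scr^-1.154 * age^-0.203 * 0.742^[female] * 1.212^[Black]`,
#' in mL/min/1.73m2. The formula is total on positive reals; no adult-range
#' clipping is applied.
#'
#' @param serum_creatinine_mg_dL serum creatinine, mg/dL (> 0)
#' @param age_years age in years (> 0)
#' @param sex `"male"` or `"female"`
#' @param black_race logical, Black race coefficient applies
#' @return numeric eGFR (vectorized)
#' @examples
#' egfr_mdrd(2.5, 60, "female", FALSE)  # ~19.6, qualifies as CKD (<= 30)
#' @export
egfr_mdrd <- function(serum_creatinine_mg_dL, age_years, sex, black_race) {
  if (any(serum_creatinine_mg_dL <= 0, na.rm = TRUE) ||
      any(age_years <= 0, na.rm = TRUE)) {
    stop("creatinine and age must be positive", call. = FALSE)
  }
  175 * serum_creatinine_mg_dL^(-1.154) * age_years^(-0.203) *
    ifelse(sex == "female", 0.742, 1) * ifelse(black_race, 1.212, 1)
}

#' Filter events to a lookback/lookforward window around an anchor
#'
#' Boundaries are inclusive on both sides: an event exactly at the anchor,
#' or exactly `lookback_days` away, is retained.
#'
#' @param events data frame of events
#' @param anchor_time anchor timestamp (POSIXct or numeric day offset)
#' @param lookback_days window length in days (> 0)
#' @param direction `"before"` (anchor - lookback <= t <= anchor) or
#'   `"after"` (anchor <= t <= anchor + lookback)
#' @param time_col name of the time column; defaults to the first column
#'   whose name ends in `_time`
#' @return the filtered events data frame
#' @export
within_window <- function(events, anchor_time, lookback_days,
                          direction = c("before", "after"),
                          time_col = NULL) {
  direction <- match.arg(direction)
  stopifnot(lookback_days > 0)
  if (is.null(time_col)) {
    time_col <- grep("_time$", names(events), value = TRUE)[1]
  }
  t <- as_days(events[[time_col]])
  a <- as_days(anchor_time)
  keep <- if (direction == "before") {
    t >= a - lookback_days & t <= a
  } else {
    t >= a & t <= a + lookback_days
  }
  events[!is.na(keep) & keep, , drop = FALSE]
}

# ---- record linkage helpers -------------------------------------------------

# Link records to admissions by encounter_id, keeping rows whose timestamp
# falls inside the admission (inclusive). Returns (encounter_id, row, t).
#' @keywords internal
#' @noRd
link_admission <- function(df, tcol, cohort) {
  adm <- cohort$admissions
  if (!nrow(df) || !nrow(adm)) {
    return(data.frame(encounter_id = character(0), row = integer(0),
                      t = numeric(0)))
  }
  m <- match(df$encounter_id, adm$encounter_id)
  t <- as_days(df[[tcol]])
  lo <- as_days(adm$admit_time)[m]
  hi <- as_days(adm$discharge_time)[m]
  keep <- !is.na(m) & !is.na(t) & t >= lo & t <= hi
  data.frame(encounter_id = df$encounter_id[keep], row = which(keep),
             t = t[keep], stringsAsFactors = FALSE)
}

# Link records to admissions at the patient level. window = "lookback":
# admit - lookback_days <= t <= discharge (lookback results plus the index
# admission's own results both count). window = "historic": t <= discharge.
#' @keywords internal
#' @noRd
link_patient <- function(df, tcol, cohort, window, lookback_days = 365) {
  adm <- cohort$admissions
  if (!nrow(df) || !nrow(adm)) {
    return(data.frame(encounter_id = character(0), row = integer(0),
                      t = numeric(0)))
  }
  enc2pat <- stats::setNames(adm$patient_id, adm$encounter_id)
  pat <- if ("patient_id" %in% names(df)) df$patient_id else rep(NA_character_, nrow(df))
  pat <- ifelse(is.na(pat) | !nzchar(pat), unname(enc2pat[df$encounter_id]), pat)
  rec <- data.frame(row = seq_len(nrow(df)), pat = pat, t = as_days(df[[tcol]]),
                    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$pat) & !is.na(rec$t), , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(encounter_id = character(0), row = integer(0),
                      t = numeric(0)))
  }
  key <- data.frame(encounter_id = adm$encounter_id, pat = adm$patient_id,
                    lo = as_days(adm$admit_time), hi = as_days(adm$discharge_time),
                    stringsAsFactors = FALSE)
  mg <- merge(rec, key, by = "pat")
  keep <- if (window == "historic") {
    mg$t <= mg$hi
  } else {
    mg$t >= mg$lo - lookback_days & mg$t <= mg$hi
  }
  mg <- mg[keep, , drop = FALSE]
  data.frame(encounter_id = mg$encounter_id, row = mg$row, t = mg$t,
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
evidence_frame <- function(encounter_id = character(0), source = character(0),
                           row = integer(0), detail = character(0)) {
  n <- length(encounter_id)
  data.frame(encounter_id = as.character(encounter_id),
             source = rep_len(as.character(source), n),
             row = as.integer(row),
             detail = rep_len(as.character(detail), n),
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
ev <- function(link, source, detail) {
  evidence_frame(link$encounter_id, source, link$row, detail)
}

# ---- rulebook ---------------------------------------------------------------

#' @keywords internal
#' @noRd
new_rule <- function(disease_name, modifier_level, icd_patterns, detect) {
  lapply(icd_patterns, parse_icd_pattern)  # malformed patterns fail at load
  structure(list(disease_name = disease_name, modifier_level = modifier_level,
                 qualifying_icd_patterns = icd_patterns, detect = detect),
            class = "phenotype_rule")
}

#' @export
print.phenotype_rule <- function(x, ...) {
  cat(sprintf("<phenotype_rule> %s [%s]  ICD: %s\n", x$disease_name,
              x$modifier_level,
              if (length(x$qualifying_icd_patterns))
                paste(x$qualifying_icd_patterns, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Build the nineteen-disease phenotype rulebook
#'
#' Returns the declarative rulebook of nineteen disease algorithms (twelve
#' CC-level, seven MCC-level) with their qualifying ICD-10 pattern lists and
#' detection predicates. The Inpatient Death rule has an empty ICD list and
#' is therefore exempt from omission flagging. Patient-level lookback
#' sources (ejection fraction, BNP, heart-failure problem list) use a
#' 365-day window before admission, inclusive, with the index admission's
#' own results also counting; HIV screens and transplant history use
#' all-time patient history up to discharge.
#'
#' @param thresholds named list of clinical thresholds as returned by
#'   [default_thresholds()], or a path to a YAML file holding overrides.
#' @return a `phenotype_rulebook`: named list of `phenotype_rule` objects
#' @examples
#' rb <- build_rulebook()
#' length(rb)                       # 19
#' rb[["Acute Pancreatitis"]]$modifier_level
#' @export
build_rulebook <- function(thresholds = default_thresholds()) {
  if (is.character(thresholds) && length(thresholds) == 1) {
    thresholds <- utils::modifyList(default_thresholds(),
                                    yaml::read_yaml(thresholds))
  }
  th <- utils::modifyList(default_thresholds(), thresholds)

  lab_during <- function(cohort, analyte_name) {
    df <- cohort$labs
    idx <- which(df$analyte == analyte_name)
    link <- link_admission(df[idx, , drop = FALSE], "collected_time", cohort)
    link$row <- idx[link$row]
    link
  }
  troponin_positive <- function(cohort) {
    df <- cohort$labs
    pos <- df$analyte == "troponin" &
      ((!is.na(df$abnormal_flag) & df$abnormal_flag == "positive") |
         (!is.na(th$troponin_threshold) & !is.na(df$numeric_value) &
            df$numeric_value > th$troponin_threshold))
    idx <- which(pos)
    link <- link_admission(df[idx, , drop = FALSE], "collected_time", cohort)
    link$row <- idx[link$row]
    link
  }
  fs_during <- function(cohort, measure_name) {
    df <- cohort$flowsheets
    idx <- which(df$measure == measure_name)
    link <- link_admission(df[idx, , drop = FALSE], "observed_time", cohort)
    link$row <- idx[link$row]
    link
  }
  thresholded <- function(link, values, keep) {
    k <- keep & !is.na(values[link$row])
    link[!is.na(k) & k, , drop = FALSE]
  }

  rules <- list(
    new_rule("Acidemia", "CC", c("E71.*", "E87.2", "E72.*"), function(cohort) {
      l <- lab_during(cohort, "arterial_pH")
      v <- cohort$labs$numeric_value
      l <- l[!is.na(v[l$row]) & v[l$row] < th$ph_max, , drop = FALSE]
      ev(l, "labs", sprintf("arterial pH %.3f", v[l$row]))
    }),
    new_rule("Bacteremia", "CC", c("R78.81", "R65.10"), function(cohort) {
      df <- cohort$cultures
      idx <- which(df$specimen == "blood" & !is.na(df$positive) & df$positive)
      l <- link_admission(df[idx, , drop = FALSE], "collected_time", cohort)
      l$row <- idx[l$row]
      n_by_enc <- table(l$encounter_id)
      ok <- names(n_by_enc)[n_by_enc >= th$min_blood_cultures]
      l <- l[l$encounter_id %in% ok, , drop = FALSE]
      ev(l, "cultures", "positive blood culture")
    }),
    new_rule("Blood Loss Anemia", "CC", "D62", function(cohort) {
      ebl <- fs_during(cohort, "intraop_blood_loss_mL")
      v <- cohort$flowsheets$value_num
      ebl <- ebl[!is.na(v[ebl$row]) & v[ebl$row] >= th$ebl_min_ml, , drop = FALSE]
      hgb <- lab_during(cohort, "hemoglobin")
      hv <- cohort$labs$numeric_value
      hgb <- hgb[!is.na(hv[hgb$row]) & hv[hgb$row] < th$hgb_max, , drop = FALSE]
      if (!nrow(ebl) || !nrow(hgb)) return(evidence_frame())
      mg <- merge(ebl, hgb, by = "encounter_id", suffixes = c("_ebl", "_hgb"))
      # anchor = surgery end carrying the blood-loss observation; window
      # (anchor, anchor + postop_window_days]
      mg <- mg[mg$t_hgb > mg$t_ebl &
                 mg$t_hgb <= mg$t_ebl + th$postop_window_days, , drop = FALSE]
      if (!nrow(mg)) return(evidence_frame())
      rbind(
        evidence_frame(mg$encounter_id, "flowsheets", mg$row_ebl,
                       sprintf("EBL %g mL", v[mg$row_ebl])),
        evidence_frame(mg$encounter_id, "labs", mg$row_hgb,
                       sprintf("post-op hemoglobin %.1f g/dL", hv[mg$row_hgb])))
    }),
    new_rule("Chronic CHF", "CC", "I50.*", function(cohort) {
      fs <- cohort$flowsheets
      labs <- cohort$labs
      i_ef <- which(fs$measure == "ejection_fraction" & !is.na(fs$value_num) &
                      fs$value_num <= th$ef_max)
      l_ef <- link_patient(fs[i_ef, , drop = FALSE], "observed_time", cohort,
                           "lookback", th$lookback_days)
      l_ef$row <- i_ef[l_ef$row]
      i_bnp <- which(labs$analyte == "BNP" & !is.na(labs$numeric_value) &
                       labs$numeric_value > th$bnp_min)
      l_bnp <- link_patient(labs[i_bnp, , drop = FALSE], "collected_time",
                            cohort, "lookback", th$lookback_days)
      l_bnp$row <- i_bnp[l_bnp$row]
      i_pl <- which(fs$measure == "problem_list_heart_failure" &
                      ((!is.na(fs$value_chr) &
                          tolower(fs$value_chr) %in% c("present", "true", "yes", "1")) |
                         (!is.na(fs$value_num) & fs$value_num == 1)))
      l_pl <- link_patient(fs[i_pl, , drop = FALSE], "observed_time", cohort,
                           "lookback", th$lookback_days)
      l_pl$row <- i_pl[l_pl$row]
      rbind(ev(l_ef, "flowsheets", sprintf("EF %g%%", fs$value_num[l_ef$row])),
            ev(l_bnp, "labs", sprintf("BNP %g pg/mL", labs$numeric_value[l_bnp$row])),
            ev(l_pl, "flowsheets", "heart failure on problem list"))
    }),
    new_rule("Chronic Kidney Disease", "CC",
             c("N18.4", "N18.5", "N18.8", "N18.9"), function(cohort) {
      l <- lab_during(cohort, "serum_creatinine")
      if (!nrow(l)) return(evidence_frame())
      adm <- cohort$admissions
      m <- match(l$encounter_id, adm$encounter_id)
      scr <- cohort$labs$numeric_value[l$row]
      ok <- !is.na(scr) & scr > 0 & !is.na(adm$age_years[m]) & adm$age_years[m] > 0
      l <- l[ok, , drop = FALSE]; m <- m[ok]; scr <- scr[ok]
      g <- egfr_mdrd(scr, adm$age_years[m], adm$sex[m],
                     adm$race_ethnicity[m] == "Black")
      keep <- g <= th$egfr_max
      ev(l[keep, , drop = FALSE], "labs",
         sprintf("MDRD eGFR %.1f (Scr %.2f mg/dL)", g[keep], scr[keep]))
    }),
    new_rule("Delirium", "CC", c("F05", "R41.4", "R40.3"), function(cohort) {
      l <- fs_during(cohort, "CAM_result")
      vc <- cohort$flowsheets$value_chr
      l <- l[!is.na(vc[l$row]) & tolower(vc[l$row]) == "positive", , drop = FALSE]
      ev(l, "flowsheets", "positive CAM screen")
    }),
    new_rule("Extremes of BMI", "CC", c("E66.2", "Z68.1", "Z68.4", "R64"),
             function(cohort) {
      l <- fs_during(cohort, "BMI")
      v <- cohort$flowsheets$value_num
      keep <- !is.na(v[l$row]) & (v[l$row] > th$bmi_high | v[l$row] < th$bmi_low)
      l <- l[keep, , drop = FALSE]
      ev(l, "flowsheets", sprintf("BMI %.1f", v[l$row]))
    }),
    new_rule("HIV", "CC", "B20", function(cohort) {
      labs <- cohort$labs
      i_scr <- which(labs$analyte == "HIV_screen" & !is.na(labs$abnormal_flag) &
                       labs$abnormal_flag == "positive")
      l_scr <- link_patient(labs[i_scr, , drop = FALSE], "collected_time",
                            cohort, "historic")
      l_scr$row <- i_scr[l_scr$row]
      med <- cohort$medications
      i_med <- which(tolower(med$drug) == "zidovudine" &
                       med$event_kind == "order_active")
      l_med <- link_admission(med[i_med, , drop = FALSE], "event_time", cohort)
      l_med$row <- i_med[l_med$row]
      rbind(ev(l_scr, "labs", "historic positive HIV screen"),
            ev(l_med, "medications", "active zidovudine order"))
    }),
    new_rule("Hyponatremia", "CC", "E87.1", function(cohort) {
      l <- lab_during(cohort, "sodium")
      v <- cohort$labs$numeric_value
      l <- l[!is.na(v[l$row]) & v[l$row] <= th$sodium_max, , drop = FALSE]
      ev(l, "labs", sprintf("sodium %g mmol/L", v[l$row]))
    }),
    new_rule("Myocardial Injury", "CC",
             c("S26.90XA", "I25.*", "I24.8", "I24.9"), function(cohort) {
      l <- troponin_positive(cohort)
      ev(l, "labs", "positive troponin")
    }),
    new_rule("Transplant", "CC", c("T86.*", "Z94.*"), function(cohort) {
      pr <- cohort$procedures
      i_tx <- which(pr$kind == "transplant_surgery")
      l_tx <- link_patient(pr[i_tx, , drop = FALSE], "event_time", cohort,
                           "historic")
      l_tx$row <- i_tx[l_tx$row]
      med <- cohort$medications
      i_med <- which(tolower(med$drug) == "tacrolimus" &
                       med$event_kind == "administration")
      l_med <- link_admission(med[i_med, , drop = FALSE], "event_time", cohort)
      l_med$row <- i_med[l_med$row]
      rbind(ev(l_tx, "procedures", "historical transplant surgery"),
            ev(l_med, "medications", "tacrolimus administration"))
    }),
    new_rule("UTI", "CC",
             c("N39.0", "O23.40", "O23.41", "O86.2", "O03.38", "O04.88",
               "O08.83", "O23.42", "O23.43"), function(cohort) {
      df <- cohort$cultures
      idx <- which(df$specimen == "urine" & !is.na(df$colony_count) &
                     df$colony_count >= th$colony_min)
      l <- link_admission(df[idx, , drop = FALSE], "collected_time", cohort)
      l$row <- idx[l$row]
      ev(l, "cultures",
         sprintf("urine culture %g CFU/mL", df$colony_count[l$row]))
    }),
    new_rule("Acute MI", "MCC", c("I21.*", "I22.*"), function(cohort) {
      trop <- troponin_positive(cohort)
      pr <- cohort$procedures
      i_st <- which(pr$kind == "coronary_stent")
      l_st <- link_admission(pr[i_st, , drop = FALSE], "event_time", cohort)
      l_st$row <- i_st[l_st$row]
      both <- intersect(trop$encounter_id, l_st$encounter_id)
      rbind(ev(trop[trop$encounter_id %in% both, , drop = FALSE], "labs",
               "positive troponin"),
            ev(l_st[l_st$encounter_id %in% both, , drop = FALSE], "procedures",
               "coronary stent implanted"))
    }),
    new_rule("Acute Pancreatitis", "MCC", "K85.*", function(cohort) {
      v <- cohort$labs$numeric_value
      l_am <- lab_during(cohort, "amylase")
      l_am <- l_am[!is.na(v[l_am$row]) & v[l_am$row] > th$amylase_min, , drop = FALSE]
      l_li <- lab_during(cohort, "lipase")
      l_li <- l_li[!is.na(v[l_li$row]) & v[l_li$row] > th$lipase_min, , drop = FALSE]
      rbind(ev(l_am, "labs", sprintf("amylase %g U/L", v[l_am$row])),
            ev(l_li, "labs", sprintf("lipase %g U/L", v[l_li$row])))
    }),
    new_rule("Altered Mental Status", "MCC", "R40.*", function(cohort) {
      l <- fs_during(cohort, "GCS_total")
      v <- cohort$flowsheets$value_num
      l <- l[!is.na(v[l$row]) & v[l$row] <= th$gcs_max, , drop = FALSE]
      ev(l, "flowsheets", sprintf("GCS %g", v[l$row]))
    }),
    new_rule("End Stage Renal Disease", "MCC", c("N18.6", "N17.0", "N17.1"),
             function(cohort) {
      l <- fs_during(cohort, "dialysis_flow")
      ev(l, "flowsheets", "dialysis flow documented")
    }),
    new_rule("Inpatient Death", "MCC", character(0), function(cohort) {
      adm <- cohort$admissions
      i <- which(!is.na(adm$died_inpatient) & adm$died_inpatient)
      evidence_frame(adm$encounter_id[i], "admissions", i, "inpatient death")
    }),
    new_rule("Respiratory Failure", "MCC", c("J96.*", "J95.*"), function(cohort) {
      fs <- cohort$flowsheets
      i_aw <- which(fs$measure == "airway_device" & !is.na(fs$value_chr) &
                      tolower(fs$value_chr) %in% c("endotracheal_tube", "hfnc"))
      l_aw <- link_admission(fs[i_aw, , drop = FALSE], "observed_time", cohort)
      l_aw$row <- i_aw[l_aw$row]
      pr <- cohort$procedures
      i_sx <- which(pr$kind == "surgery_case")
      l_sx <- link_admission(pr[i_sx, , drop = FALSE], "event_time", cohort)
      # exclusion: no surgical procedures during the index admission
      l_aw <- l_aw[!(l_aw$encounter_id %in% l_sx$encounter_id), , drop = FALSE]
      ev(l_aw, "flowsheets",
         sprintf("airway device: %s", fs$value_chr[l_aw$row]))
    }),
    new_rule("Severe Malnutrition", "MCC",
             c("E40.*", "E41.*", "E42.*", "E43.*"), function(cohort) {
      med <- cohort$medications
      i <- which(toupper(med$drug) == "TPN")
      l <- link_admission(med[i, , drop = FALSE], "event_time", cohort)
      l$row <- i[l$row]
      ev(l, "medications", "total parenteral nutrition")
    })
  )
  names(rules) <- vapply(rules, `[[`, character(1), "disease_name")
  structure(rules, class = "phenotype_rulebook", thresholds = th)
}

#' @export
print.phenotype_rulebook <- function(x, ...) {
  cat(sprintf("<phenotype_rulebook> %d disease algorithms (%d CC, %d MCC)\n",
              length(x),
              sum(vapply(x, `[[`, character(1), "modifier_level") == "CC"),
              sum(vapply(x, `[[`, character(1), "modifier_level") == "MCC")))
  for (r in x) print(r)
  invisible(x)
}

#' Evaluate one phenotype rule for one admission
#'
#' @param rule a `phenotype_rule`
#' @param admission an `encounter_id` string, or a one-row slice of the
#'   admissions table
#' @param cohort the `ehr_cohort` the admission belongs to
#' @return a `phenotype_call`: list with `encounter_id`, `disease_name`,
#'   `detected`, and an `evidence` data frame of satisfying records
#'   (`detected` is `TRUE` iff `evidence` has rows). Records with a missing
#'   numeric value for a thresholded analyte never satisfy a rule.
#' @export
evaluate_rule <- function(rule, admission, cohort) {
  stopifnot(inherits(rule, "phenotype_rule"), inherits(cohort, "ehr_cohort"))
  enc <- if (is.character(admission)) admission else admission$encounter_id
  stopifnot(length(enc) == 1, enc %in% cohort$admissions$encounter_id)
  evd <- rule$detect(cohort)
  evd <- evd[evd$encounter_id == enc, , drop = FALSE]
  structure(list(encounter_id = enc, disease_name = rule$disease_name,
                 detected = nrow(evd) > 0, evidence = evd),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s / %s: %s (%d evidence record%s)\n",
              x$encounter_id, x$disease_name,
              if (x$detected) "DETECTED" else "not detected",
              nrow(x$evidence), if (nrow(x$evidence) == 1) "" else "s"))
  invisible(x)
}

#' Evaluate the full rulebook over every admission
#'
#' Produces one call per admission x rule (so `nrow` is `n_admissions * 19`
#' for the default rulebook). Evaluation is deterministic and invariant
#' under permutation of the clinical record tables.
#'
#' @param rulebook a `phenotype_rulebook`
#' @param cohort an `ehr_cohort`
#' @return data frame with columns `encounter_id`, `disease_name`,
#'   `modifier_level`, `detected`, `n_evidence`, plus an `evidence`
#'   list-column of per-call evidence data frames
#' @export
evaluate_cohort <- function(rulebook, cohort) {
  stopifnot(inherits(rulebook, "phenotype_rulebook"),
            inherits(cohort, "ehr_cohort"))
  encs <- cohort$admissions$encounter_id
  if (!length(encs)) {
    out <- data.frame(encounter_id = character(0), disease_name = character(0),
                      modifier_level = character(0), detected = logical(0),
                      n_evidence = integer(0), stringsAsFactors = FALSE)
    out$evidence <- list()
    return(out)
  }
  blocks <- lapply(rulebook, function(rule) {
    evd <- rule$detect(cohort)
    evd <- evd[order(evd$row), , drop = FALSE]
    by_enc <- if (nrow(evd)) split(evd, evd$encounter_id) else list()
    n_ev <- integer(length(encs))
    hit <- match(encs, names(by_enc))
    n_ev[!is.na(hit)] <- vapply(by_enc, nrow, integer(1))[hit[!is.na(hit)]]
    blk <- data.frame(encounter_id = encs, disease_name = rule$disease_name,
                      modifier_level = rule$modifier_level,
                      detected = n_ev > 0, n_evidence = n_ev,
                      stringsAsFactors = FALSE)
    evlist <- rep(list(evidence_frame()), length(encs))
    evlist[!is.na(hit)] <- by_enc[hit[!is.na(hit)]]
    blk$evidence <- evlist
    blk
  })
  out <- do.call(rbind, blocks)
  out <- out[order(match(out$encounter_id, encs),
                   match(out$disease_name, names(rulebook))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
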