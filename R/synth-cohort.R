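# Seeded synthetic EHR cohort generator. Latent disease states are drawn per
# admission, rule-satisfying clinical records are injected for every true
# disease (values drawn just past the thresholds), qualifying ICD codes are
# emitted with a configurable per-disease omission probability, and billed
# DRGs are drawn at or below the clinically required severity level under a
# configurable under-coding scheme. Negative admissions receive only records
# strictly on the safe side of every threshold, so on this noiseless data
# the pipeline must reproduce the latent truth table exactly.

DISEASES <- c("Acidemia", "Acute MI", "Bacteremia", "Blood Loss Anemia",
              "Chronic CHF", "Chronic Kidney Disease", "Delirium",
              "Extremes of BMI", "HIV", "Hyponatremia", "Myocardial Injury",
              "Transplant", "UTI", "Acute Pancreatitis",
              "Altered Mental Status", "End Stage Renal Disease",
              "Inpatient Death", "Respiratory Failure", "Severe Malnutrition")

RULE_LEVELS <- c(
  "Acidemia" = "CC", "Bacteremia" = "CC", "Blood Loss Anemia" = "CC",
  "Chronic CHF" = "CC", "Chronic Kidney Disease" = "CC", "Delirium" = "CC",
  "Extremes of BMI" = "CC", "HIV" = "CC", "Hyponatremia" = "CC",
  "Myocardial Injury" = "CC", "Transplant" = "CC", "UTI" = "CC",
  "Acute MI" = "MCC", "Acute Pancreatitis" = "MCC",
  "Altered Mental Status" = "MCC", "End Stage Renal Disease" = "MCC",
  "Inpatient Death" = "MCC", "Respiratory Failure" = "MCC",
  "Severe Malnutrition" = "MCC")

# one concrete billable code per disease, chosen so that no representative
# code (nor the Z00.xx filler pool) matches another disease's pattern list
REPRESENTATIVE_ICD <- c(
  "Acidemia" = "E87.2", "Acute MI" = "I21.9", "Bacteremia" = "R78.81",
  "Blood Loss Anemia" = "D62", "Chronic CHF" = "I50.9",
  "Chronic Kidney Disease" = "N18.4", "Delirium" = "F05",
  "Extremes of BMI" = "E66.2", "HIV" = "B20", "Hyponatremia" = "E87.1",
  "Myocardial Injury" = "I24.8", "Transplant" = "Z94.0", "UTI" = "N39.0",
  "Acute Pancreatitis" = "K85.90", "Altered Mental Status" = "R40.20",
  "End Stage Renal Disease" = "N18.6", "Inpatient Death" = NA_character_,
  "Respiratory Failure" = "J96.00", "Severe Malnutrition" = "E43")

#' Default per-disease rates for the synthetic generator
#'
#' Prevalence, ICD-omission, and algorithm-insensitivity (qualifying code
#' present without clinical evidence) rates emulating the disease-frequency
#' structure of a large academic-center inpatient year (tens of thousands
#' of admissions): common laboratory phenotypes such as hyponatremia near
#' 29% prevalence with omission rates above 60%, rare procedure-defined
#' phenotypes such as acute MI below 0.1%.
#'
#' @return data frame: `disease_name`, `prevalence`, `omission_rate`,
#'   `not_sensitive_rate`
#' @export
default_disease_rates <- function() {
  data.frame(
    disease_name = DISEASES,
    prevalence = c(0.0719, 0.0009, 0.0227, 0.0334, 0.0400, 0.1268, 0.0208,
                   0.1153, 0.0088, 0.2865, 0.0771, 0.0821, 0.0606, 0.0066,
                   0.1014, 0.0158, 0.0277, 0.0250, 0.0233),
    omission_rate = c(0.632, 0.125, 0.252, 0.267, 0.215, 0.245, 0.803,
                      0.468, 0.070, 0.623, 0.371, 0.040, 0.291, 0.200,
                      0.496, 0.160, 0.000, 0.039, 0.579),
    not_sensitive_rate = c(0.0603, 0.0589, 0.0320, 0.1178, 0.1283, 0.1148,
                           0.0189, 0.0319, 0.0019, 0.0057, 0.1560, 0.0174,
                           0.0503, 0.0081, 0.1003, 0.0822, 0.0000, 0.1343,
                           0.0520),
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort: size, seed, per-disease
#' rates, DRG catalogue and under-coding behaviour, payor and demographic
#' mixes. Defaults emulate the cohort structure of a large academic-center
#' inpatient year: a 10.8% Singlet DRG share, a payor mix of roughly 14%
#' Medi-Cal / 38% Medicare / 48% private, and the demographic mix of an
#' urban tertiary center. All mixes must sum to 1.
#'
#' @param n_admissions number of admissions to simulate
#' @param seed RNG seed; identical config + seed reproduce the cohort
#'   byte-for-byte
#' @param disease_rates data frame as [default_disease_rates()]
#' @param prevalence,omission_rate,not_sensitive_rate optional named
#'   per-disease overrides applied on top of `disease_rates`
#' @param drg_catalogue a `drg_catalogue` (default: the shipped synthetic
#'   catalogue) or a CSV path; at least one family must offer Base, CC and
#'   MCC arms
#' @param singlet_fraction fraction of admissions billed under a Singlet DRG
#' @param undercode_u under-coding intensity `u`: a billed DRG sits one
#'   level below the required level with probability `u`, two levels below
#'   with probability `u^2/2` (renormalized when fewer steps exist), else
#'   at the required level
#' @param payor_mix,sex_mix,race_mix,age_mix named fraction vectors summing
#'   to 1 (age bands: `18-35`, `36-64`, `65-78`, `79+`)
#' @param background_rate probability a disease-negative admission receives
#'   a safe-side (non-qualifying) record for that disease
#' @param icd_padding number of filler codes appended to every admission's
#'   billed list (exercises payor code-count limits)
#' @return a `synth_config` list
#' @export
synth_config <- function(n_admissions = 500, seed = 1,
                         disease_rates = default_disease_rates(),
                         prevalence = NULL, omission_rate = NULL,
                         not_sensitive_rate = NULL,
                         drg_catalogue = synthetic_drg_catalogue(),
                         singlet_fraction = 0.108, undercode_u = 0.3,
                         payor_mix = c("MEDI-CAL" = 0.140, "MEDICARE" = 0.383,
                                       "PRIVATE" = 0.477),
                         sex_mix = c(male = 0.461, female = 0.539),
                         race_mix = c("Asian/Pacific Islander" = 0.0979,
                                      "Black" = 0.0981,
                                      "Caucasian-Hispanic" = 0.0767,
                                      "Caucasian-Non-Hispanic" = 0.5127,
                                      "Other-Hispanic" = 0.1317,
                                      "Other-Non-Hispanic" = 0.0829),
                         age_mix = c("18-35" = 0.2173, "36-64" = 0.4251,
                                     "65-78" = 0.2462, "79+" = 0.1114),
                         background_rate = 0.25, icd_padding = 0) {
  rates <- disease_rates
  stopifnot(setequal(rates$disease_name, DISEASES))
  rownames(rates) <- rates$disease_name
  overrides <- list(prevalence = prevalence, omission_rate = omission_rate,
                    not_sensitive_rate = not_sensitive_rate)
  for (ov in names(overrides)) {
    v <- overrides[[ov]]
    if (!is.null(v)) rates[names(v), ov] <- v
  }
  for (cl in c("prevalence", "omission_rate", "not_sensitive_rate")) {
    if (any(is.na(rates[[cl]])) || any(rates[[cl]] < 0 | rates[[cl]] > 1)) {
      stop(sprintf("%s must lie in [0, 1]", cl), call. = FALSE)
    }
  }
  mixes <- list(payor_mix = payor_mix, sex_mix = sex_mix,
                race_mix = race_mix, age_mix = age_mix)
  for (mn in names(mixes)) {
    if (abs(sum(mixes[[mn]]) - 1) > 1e-9) {
      stop(sprintf("%s must sum to 1", mn), call. = FALSE)
    }
  }
  if (!inherits(drg_catalogue, "drg_catalogue")) {
    drg_catalogue <- load_drg_catalogue(drg_catalogue)
  }
  lev_fams <- names(which(tapply(drg_catalogue$level, drg_catalogue$family,
                                 function(l) all(c("BASE", "CC", "MCC") %in% l))))
  if (!length(lev_fams)) {
    stop("drg_catalogue offers no family with all of BASE, CC and MCC levels",
         call. = FALSE)
  }
  if (singlet_fraction > 0 && !any(drg_catalogue$level == "SINGLET")) {
    stop("singlet_fraction > 0 but the catalogue has no SINGLET entry",
         call. = FALSE)
  }
  structure(list(n_admissions = n_admissions, seed = seed, rates = rates,
                 drg_catalogue = drg_catalogue, leveled_families = lev_fams,
                 singlet_fraction = singlet_fraction, undercode_u = undercode_u,
                 payor_mix = payor_mix, sex_mix = sex_mix, race_mix = race_mix,
                 age_mix = age_mix, background_rate = background_rate,
                 icd_padding = icd_padding),
            class = "synth_config")
}

#' The shipped synthetic DRG mini-catalogue
#'
#' Twelve fully-tiered families (Base/CC/MCC arms with strictly increasing
#' relative weighting factors), one doublet family, and two Singlet entries.
#' Entirely synthetic: codes and weights are invented for testing and
#' demonstration, not CMS values.
#'
#' @return a `drg_catalogue`
#' @export
synthetic_drg_catalogue <- function() {
  path <- system.file("extdata", "drg_catalogue_synthetic.csv",
                      package = "drgaudit")
  load_drg_catalogue(path)
}

#' @keywords internal
#' @noRd
rcat <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = unname(mix))
}

#' Generate a synthetic cohort and its latent truth
#'
#' Deterministic given the config's seed. Every admission draws its disease
#' set independently per prevalence; each true disease injects
#' rule-satisfying clinical records and emits its qualifying ICD code with
#' probability one minus the omission rate; the billed DRG sits at or below
#' the required severity level per the under-coding scheme. Two latent
#' draws are reconciled for internal consistency and recorded as drawn:
#' Acute MI forces Myocardial Injury (the positive-troponin criterion is
#' shared), and Blood Loss Anemia suppresses Respiratory Failure (whose
#' rule demands a surgery-free admission).
#'
#' @param config a [synth_config()]
#' @return list with elements `cohort` (an `ehr_cohort`) and `truth` (a
#'   `latent_truth`: per-admission disease/omission labels and DRG
#'   assignment, the answer key for [truth_table()])
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_admissions
  rates <- config$rates
  cat_ <- config$drg_catalogue

  enc <- sprintf("enc%05d", seq_len(n))
  pat <- sprintf("pt%05d", seq_len(n))
  t0 <- as.numeric(as.POSIXct("2019-01-01 00:00:00", tz = "UTC"))
  admit <- t0 + round(stats::runif(n, 0, 364) * SECONDS_PER_DAY)
  los <- stats::runif(n, 1, 10)
  discharge <- admit + round(los * SECONDS_PER_DAY)

  sex <- rcat(n, config$sex_mix)
  race <- rcat(n, config$race_mix)
  band <- rcat(n, config$age_mix)
  age_lo <- c("18-35" = 18, "36-64" = 36, "65-78" = 65, "79+" = 79)[band]
  age_hi <- c("18-35" = 35, "36-64" = 64, "65-78" = 78, "79+" = 95)[band]
  age <- round(stats::runif(n, age_lo, age_hi), 1)
  payor_class <- rcat(n, config$payor_mix)
  raw_labels <- list("MEDI-CAL" = c("Medi-Cal", "Medicaid"),
                     "MEDICARE" = c("Medicare", "Medicare Advantage"),
                     "PRIVATE" = c("Blue Cross PPO", "Aetna HMO",
                                   "United PPO", "Cigna EPO"))
  raw_fc <- vapply(payor_class, function(pc) sample(raw_labels[[pc]], 1),
                   character(1), USE.NAMES = FALSE)

  # latent disease draws, then the two consistency reconciliations
  L <- vapply(DISEASES, function(d)
    stats::runif(n) < rates[d, "prevalence"], logical(n))
  if (n == 1) L <- matrix(L, nrow = 1, dimnames = list(NULL, DISEASES))
  L[, "Myocardial Injury"] <- L[, "Myocardial Injury"] | L[, "Acute MI"]
  L[, "Respiratory Failure"] <- L[, "Respiratory Failure"] &
    !L[, "Blood Loss Anemia"]
  died <- L[, "Inpatient Death"]

  # DRG assignment: required level from the latent disease set, billed level
  # drawn at or below it under the under-coding scheme
  lev_of <- function(v) c("BASE", "CC", "MCC")[v + 1]
  dis_val <- ifelse(RULE_LEVELS[DISEASES] == "MCC", 2L, 1L)
  req_val <- apply(L, 1, function(row) {
    if (!any(row)) 0L else max(dis_val[row])
  })
  is_singlet <- stats::runif(n) < config$singlet_fraction
  fam <- sample(config$leveled_families, n, replace = TRUE)
  u <- config$undercode_u
  billed_val <- vapply(req_val, function(r) {
    if (r == 0L) return(0L)
    w <- c(1 - u - if (r == 2L) u^2 / 2 else 0, u, if (r == 2L) u^2 / 2)
    w <- pmax(w, 1e-12)
    as.integer(r - sample(0:r, 1, prob = w / sum(w)))
  }, integer(1))
  singlet_pool <- cat_$drg_code[cat_$level == "SINGLET"]
  code_by_fam_lev <- cat_$drg_code
  names(code_by_fam_lev) <- paste(cat_$family, cat_$level, sep = "\r")
  billed_code <- ifelse(is_singlet,
                        sample(singlet_pool, n, replace = TRUE),
                        unname(code_by_fam_lev[paste(fam, lev_of(billed_val),
                                                     sep = "\r")]))
  if (any(is.na(billed_code))) {
    stop(sprintf("catalogue family '%s' lacks a required level",
                 fam[which(is.na(billed_code))[1]]), call. = FALSE)
  }

  # record accumulators: rows pushed as lists, materialized once at the end
  acc <- list(labs = list(), cultures = list(), flows = list(),
              meds = list(), procs = list())
  push <- function(tab, row) acc[[tab]][[length(acc[[tab]]) + 1]] <<- row
  add_lab <- function(i, t, analyte, value = NA_real_, flag = NA_character_,
                      patient_level = FALSE) {
    push("labs", list(enc = if (patient_level) NA_character_ else enc[i],
                      pat = pat[i], t = t, analyte = analyte,
                      value = round(value, 4), flag = flag))
  }
  add_culture <- function(i, t, specimen, positive, colony = NA_real_) {
    push("cultures", list(enc = enc[i], t = t, specimen = specimen,
                          positive = positive, colony = round(colony)))
  }
  add_flow <- function(i, t, measure, vnum = NA_real_, vchr = NA_character_,
                       patient_level = FALSE) {
    push("flows", list(enc = if (patient_level) NA_character_ else enc[i],
                       pat = pat[i], t = t, measure = measure,
                       vnum = round(vnum, 4), vchr = vchr))
  }
  add_med <- function(i, t, drug, kind) {
    push("meds", list(enc = enc[i], pat = pat[i], t = t, drug = drug,
                      kind = kind))
  }
  add_proc <- function(i, t, kind, cpt = NA_character_,
                       patient_level = FALSE) {
    push("procs", list(enc = if (patient_level) NA_character_ else enc[i],
                       pat = pat[i], t = t, kind = kind, cpt = cpt))
  }
  t_intra <- function(i, frac = stats::runif(1, 0.05, 0.95)) {
    admit[i] + round(frac * los[i] * SECONDS_PER_DAY)
  }
  t_lookback <- function(i, max_days = 300) {
    admit[i] - round(stats::runif(1, 5, max_days) * SECONDS_PER_DAY)
  }
  pos <- function(d) which(L[, d])
  bg <- function(d, extra_ok = rep(TRUE, n)) {
    idx <- which(!L[, d] & extra_ok)
    idx[stats::runif(length(idx)) < config$background_rate]
  }
  scr_for_egfr <- function(i, target_egfr) {
    f <- ifelse(sex[i] == "female", 0.742, 1) *
      ifelse(race[i] == "Black", 1.212, 1)
    (175 * age[i]^(-0.203) * f / target_egfr)^(1 / 1.154)
  }

  # --- positives: rule-satisfying records just past each threshold --------
  for (i in pos("Acidemia")) add_lab(i, t_intra(i), "arterial_pH",
                                     stats::runif(1, 7.20, 7.349), "abnormal")
  for (i in pos("Bacteremia")) {
    for (j in seq_len(2 + stats::rbinom(1, 1, 0.3))) {
      add_culture(i, t_intra(i), "blood", TRUE)
    }
  }
  for (i in pos("Blood Loss Anemia")) {
    ts <- t_intra(i, stats::runif(1, 0.05, 0.5))
    add_proc(i, ts, "surgery_case", "33510")
    add_flow(i, ts, "intraop_blood_loss_mL", stats::runif(1, 300, 1200))
    room <- min(0.9, 0.9 * (discharge[i] - ts) / SECONDS_PER_DAY)
    add_lab(i, ts + round(stats::runif(1, 0.04, room) * SECONDS_PER_DAY),
            "hemoglobin", stats::runif(1, 8.5, 11.9))
  }
  for (i in pos("Chronic CHF")) {
    mech <- sample(c("EF", "BNP", "PL"), 1)
    tl <- t_lookback(i)
    if (mech == "EF") {
      add_flow(i, tl, "ejection_fraction", stats::runif(1, 10, 30),
               patient_level = TRUE)
    } else if (mech == "BNP") {
      add_lab(i, tl, "BNP", stats::runif(1, 950, 5000), patient_level = TRUE)
    } else {
      add_flow(i, tl, "problem_list_heart_failure", vchr = "present",
               patient_level = TRUE)
    }
  }
  for (i in pos("Chronic Kidney Disease")) {
    add_lab(i, t_intra(i), "serum_creatinine",
            scr_for_egfr(i, 30) * stats::runif(1, 1.02, 1.6))
  }
  for (i in pos("Delirium")) add_flow(i, t_intra(i), "CAM_result",
                                      vchr = "positive")
  for (i in pos("Extremes of BMI")) {
    v <- if (stats::runif(1) < 0.5) stats::runif(1, 40.1, 55) else
      stats::runif(1, 14, 18.9)
    add_flow(i, t_intra(i), "BMI", v)
  }
  for (i in pos("HIV")) {
    if (stats::runif(1) < 0.5) {
      add_lab(i, t_lookback(i, 2000), "HIV_screen", flag = "positive",
              patient_level = TRUE)
    } else {
      add_med(i, t_intra(i), "zidovudine", "order_active")
    }
  }
  for (i in pos("Hyponatremia")) add_lab(i, t_intra(i), "sodium",
                                         stats::runif(1, 122, 134))
  for (i in pos("Myocardial Injury")) add_lab(i, t_intra(i), "troponin",
                                              stats::runif(1, 0.5, 10),
                                              "positive")
  for (i in pos("Transplant")) {
    if (stats::runif(1) < 0.5) {
      add_proc(i, t_lookback(i, 3000), "transplant_surgery",
               patient_level = TRUE)
    } else {
      add_med(i, t_intra(i), "tacrolimus", "administration")
    }
  }
  for (i in pos("UTI")) add_culture(i, t_intra(i), "urine", TRUE,
                                    stats::runif(1, 1e5, 5e6))
  for (i in pos("Acute MI")) add_proc(i, t_intra(i), "coronary_stent", "92928")
  for (i in pos("Acute Pancreatitis")) {
    if (stats::runif(1) < 0.5) {
      add_lab(i, t_intra(i), "amylase", stats::runif(1, 1100, 4000))
    } else {
      add_lab(i, t_intra(i), "lipase", stats::runif(1, 500, 2500))
    }
  }
  for (i in pos("Altered Mental Status")) add_flow(i, t_intra(i), "GCS_total",
                                                   sample(3:8, 1))
  for (i in pos("End Stage Renal Disease")) {
    add_flow(i, t_intra(i), "dialysis_flow", stats::runif(1, 200, 400))
  }
  for (i in pos("Respiratory Failure")) {
    add_flow(i, t_intra(i), "airway_device",
             vchr = sample(c("endotracheal_tube", "HFNC"), 1))
  }
  for (i in pos("Severe Malnutrition")) add_med(i, t_intra(i), "TPN",
                                                "administration")

  # --- negatives: safe-side background records ----------------------------
  for (i in bg("Acidemia")) add_lab(i, t_intra(i), "arterial_pH",
                                    stats::runif(1, 7.36, 7.45), "normal")
  for (i in bg("Bacteremia")) {
    # a single positive blood culture never satisfies the two-culture rule
    add_culture(i, t_intra(i), "blood", stats::runif(1) < 0.5)
  }
  no_rf <- !L[, "Respiratory Failure"]
  for (i in bg("Blood Loss Anemia", no_rf)) {
    ts <- t_intra(i, stats::runif(1, 0.05, 0.5))
    add_proc(i, ts, "surgery_case", "33510")
    if (stats::runif(1) < 0.5) {
      add_flow(i, ts, "intraop_blood_loss_mL", stats::runif(1, 50, 250))
      add_lab(i, ts + round(stats::runif(1, 0.05, 0.5) * SECONDS_PER_DAY),
              "hemoglobin", stats::runif(1, 8.5, 11.9))
    } else {
      add_flow(i, ts, "intraop_blood_loss_mL", stats::runif(1, 300, 1200))
      add_lab(i, ts + round(stats::runif(1, 0.05, 0.5) * SECONDS_PER_DAY),
              "hemoglobin", stats::runif(1, 12.1, 15.5))
    }
  }
  for (i in bg("Chronic CHF")) {
    if (stats::runif(1) < 0.5) {
      add_flow(i, t_lookback(i), "ejection_fraction", stats::runif(1, 40, 70),
               patient_level = TRUE)
    } else {
      add_lab(i, t_lookback(i), "BNP", stats::runif(1, 50, 850),
              patient_level = TRUE)
    }
  }
  for (i in bg("Chronic Kidney Disease")) {
    add_lab(i, t_intra(i), "serum_creatinine",
            scr_for_egfr(i, 35) * stats::runif(1, 0.5, 0.95))
  }
  for (i in bg("Delirium")) add_flow(i, t_intra(i), "CAM_result",
                                     vchr = "negative")
  for (i in bg("Extremes of BMI")) add_flow(i, t_intra(i), "BMI",
                                            stats::runif(1, 20, 39))
  for (i in bg("HIV")) add_lab(i, t_lookback(i, 2000), "HIV_screen",
                               flag = "negative", patient_level = TRUE)
  for (i in bg("Hyponatremia")) add_lab(i, t_intra(i), "sodium",
                                        stats::runif(1, 136, 144))
  for (i in bg("Myocardial Injury")) add_lab(i, t_intra(i), "troponin",
                                             stats::runif(1, 0, 0.02),
                                             "negative")
  for (i in bg("Acute MI", !L[, "Myocardial Injury"])) {
    # a stent without a positive troponin never satisfies the MI rule
    add_proc(i, t_intra(i), "coronary_stent", "92928")
  }
  for (i in bg("Acute Pancreatitis")) {
    if (stats::runif(1) < 0.5) {
      add_lab(i, t_intra(i), "amylase", stats::runif(1, 30, 900))
    } else {
      add_lab(i, t_intra(i), "lipase", stats::runif(1, 10, 400))
    }
  }
  for (i in bg("Altered Mental Status")) add_flow(i, t_intra(i), "GCS_total",
                                                  sample(9:15, 1))
  for (i in bg("UTI")) add_culture(i, t_intra(i), "urine", FALSE,
                                   stats::runif(1, 1e3, 9e4))
  for (i in bg("Respiratory Failure", no_rf)) {
    # airway support is always paired with a surgery so the no-surgery
    # exclusion keeps the rule negative
    add_flow(i, t_intra(i, stats::runif(1, 0.1, 0.5)), "airway_device",
             vchr = sample(c("endotracheal_tube", "HFNC"), 1))
    add_proc(i, t_intra(i), "surgery_case", "47562")
  }

  # --- ICD emission --------------------------------------------------------
  icd_list <- vector("list", n)
  omitted <- matrix(FALSE, n, length(DISEASES),
                    dimnames = list(NULL, DISEASES))
  for (d in DISEASES) {
    code <- REPRESENTATIVE_ICD[[d]]
    if (is.na(code)) next
    p_idx <- pos(d)
    om <- stats::runif(length(p_idx)) < rates[d, "omission_rate"]
    omitted[p_idx, d] <- om
    for (i in p_idx[!om]) icd_list[[i]] <- c(icd_list[[i]], code)
    nn <- which(!L[, d])
    for (i in nn[stats::runif(length(nn)) < rates[d, "not_sensitive_rate"]]) {
      icd_list[[i]] <- c(icd_list[[i]], code)
    }
  }
  if (config$icd_padding > 0) {
    filler <- sprintf("Z00.%02d", seq_len(config$icd_padding) - 1)
    icd_list <- lapply(icd_list, c, filler)
  }

  # --- materialize tables --------------------------------------------------
  col <- function(rows, f, type) {
    if (!length(rows)) return(vector(mode = type, length = 0))
    vapply(rows, function(r) {
      v <- r[[f]]
      if (is.null(v) || length(v) == 0) v <- NA
      as.vector(v, mode = type)
    }, vector(mode = type, 1))
  }
  tstamp <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  labs_df <- data.frame(
    encounter_id = col(acc$labs, "enc", "character"),
    patient_id = col(acc$labs, "pat", "character"),
    collected_time = tstamp(col(acc$labs, "t", "double")),
    analyte = col(acc$labs, "analyte", "character"),
    numeric_value = col(acc$labs, "value", "double"),
    abnormal_flag = col(acc$labs, "flag", "character"),
    stringsAsFactors = FALSE)
  cultures_df <- data.frame(
    encounter_id = col(acc$cultures, "enc", "character"),
    collected_time = tstamp(col(acc$cultures, "t", "double")),
    specimen = col(acc$cultures, "specimen", "character"),
    positive = col(acc$cultures, "positive", "logical"),
    colony_count = col(acc$cultures, "colony", "double"),
    stringsAsFactors = FALSE)
  flows_df <- data.frame(
    encounter_id = col(acc$flows, "enc", "character"),
    patient_id = col(acc$flows, "pat", "character"),
    observed_time = tstamp(col(acc$flows, "t", "double")),
    measure = col(acc$flows, "measure", "character"),
    value_num = col(acc$flows, "vnum", "double"),
    value_chr = col(acc$flows, "vchr", "character"),
    stringsAsFactors = FALSE)
  meds_df <- data.frame(
    encounter_id = col(acc$meds, "enc", "character"),
    patient_id = col(acc$meds, "pat", "character"),
    event_time = tstamp(col(acc$meds, "t", "double")),
    drug = col(acc$meds, "drug", "character"),
    event_kind = col(acc$meds, "kind", "character"),
    stringsAsFactors = FALSE)
  procs_df <- data.frame(
    encounter_id = col(acc$procs, "enc", "character"),
    patient_id = col(acc$procs, "pat", "character"),
    event_time = tstamp(col(acc$procs, "t", "double")),
    kind = col(acc$procs, "kind", "character"),
    cpt_codes = col(acc$procs, "cpt", "character"),
    stringsAsFactors = FALSE)

  admissions <- data.frame(
    encounter_id = enc, patient_id = pat, admit_time = tstamp(admit),
    discharge_time = tstamp(discharge), died_inpatient = died,
    raw_financial_class = raw_fc, sex = sex, race_ethnicity = race,
    age_years = age, billed_icd_codes = join_icd_list(icd_list),
    billed_drg_code = billed_code, stringsAsFactors = FALSE)
  cohort <- ehr_cohort(admissions = admissions, labs = labs_df,
                       cultures = cultures_df, flowsheets = flows_df,
                       medications = meds_df, procedures = procs_df)

  truth <- structure(list(
    admissions = data.frame(
      encounter_id = enc, payor_class = payor_class,
      required_value = req_val,
      billed_value = ifelse(is_singlet, NA_integer_, billed_val),
      billed_drg = billed_code, singlet = is_singlet,
      family = ifelse(is_singlet, NA_character_, fam),
      emitted_icd = join_icd_list(icd_list), stringsAsFactors = FALSE),
    diseases = data.frame(
      encounter_id = rep(enc, each = length(DISEASES)),
      disease_name = rep(DISEASES, n),
      present = as.vector(t(L)), icd_omitted = as.vector(t(omitted)),
      stringsAsFactors = FALSE),
    catalogue = cat_), class = "latent_truth")
  list(cohort = cohort, truth = truth)
}

#' Expected pipeline output for a synthetic cohort
#'
#' Derives, from the latent truth alone, the answer key the audit pipeline
#' must reproduce exactly on noiseless synthetic data: one omission finding
#' per admission x disease and one DRG upgrade flag per admission.
#'
#' @param truth a `latent_truth` from [generate_cohort()]
#' @param rulebook the `phenotype_rulebook` (for qualifying ICD patterns
#'   and modifier levels)
#' @return list with `findings` (`encounter_id`, `disease_name`, `detected`,
#'   `icd_present`, `missing_icd`) and `upgrades` (`encounter_id`,
#'   `upgrade_type`, `delta_rwf`)
#' @export
truth_table <- function(truth, rulebook = build_rulebook()) {
  stopifnot(inherits(truth, "latent_truth"))
  ta <- truth$admissions
  td <- truth$diseases
  codes <- split_icd_list(ta$emitted_icd)
  pat_by_dis <- lapply(rulebook, `[[`, "qualifying_icd_patterns")
  pm <- vapply(rulebook, function(rule) {
    parsed <- lapply(rule$qualifying_icd_patterns, parse_icd_pattern)
    vapply(codes, function(cc) any_icd_match_parsed(parsed, cc), logical(1))
  }, logical(max(1, nrow(ta))))
  if (nrow(ta) == 1) pm <- matrix(pm, nrow = 1,
                                  dimnames = list(NULL, names(rulebook)))
  present_code <- pm[cbind(match(td$encounter_id, ta$encounter_id),
                           match(td$disease_name, colnames(pm)))]
  findings <- data.frame(
    encounter_id = td$encounter_id, disease_name = td$disease_name,
    detected = td$present, icd_present = unname(present_code),
    missing_icd = td$present & !present_code &
      unname(lengths(pat_by_dis)[td$disease_name] > 0),
    stringsAsFactors = FALSE)

  cat_ <- truth$catalogue
  lev_of <- function(v) c("BASE", "CC", "MCC")[v + 1]
  rwf_key <- stats::setNames(cat_$rwf, paste(cat_$family, cat_$level, sep = "\r"))
  ups <- lapply(seq_len(nrow(ta)), function(i) {
    r <- ta$required_value[i]
    b <- ta$billed_value[i]
    if (ta$singlet[i] || is.na(b) || r <= b) {
      return(data.frame(encounter_id = ta$encounter_id[i],
                        upgrade_type = "none", delta_rwf = 0,
                        stringsAsFactors = FALSE))
    }
    type <- if (b == 0L && r == 1L) "base_to_CC" else
      if (b == 0L) "base_to_MCC" else "CC_to_MCC"
    delta <- unname(rwf_key[paste(ta$family[i], lev_of(r), sep = "\r")] -
                      rwf_key[paste(ta$family[i], lev_of(b), sep = "\r")])
    data.frame(encounter_id = ta$encounter_id[i], upgrade_type = type,
               delta_rwf = delta, stringsAsFactors = FALSE)
  })
  list(findings = findings, upgrades = do.call(rbind, ups))
}
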