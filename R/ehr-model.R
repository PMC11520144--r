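# Domain model for structured EHR extracts: one admissions table plus five
# clinical source tables (labs, cultures, flowsheets, medications,
# procedures), linked by encounter_id and -- for lookback sources that may
# predate the index encounter -- by patient_id.

# canonical column sets; order is the on-disk column order
COHORT_SCHEMA <- list(
  admissions = c("encounter_id", "patient_id", "admit_time", "discharge_time",
                 "died_inpatient", "raw_financial_class", "sex",
                 "race_ethnicity", "age_years", "billed_icd_codes",
                 "billed_drg_code"),
  labs        = c("encounter_id", "patient_id", "collected_time", "analyte",
                  "numeric_value", "abnormal_flag"),
  cultures    = c("encounter_id", "collected_time", "specimen", "positive",
                  "colony_count"),
  flowsheets  = c("encounter_id", "patient_id", "observed_time", "measure",
                  "value_num", "value_chr"),
  medications = c("encounter_id", "patient_id", "event_time", "drug",
                  "event_kind"),
  procedures  = c("encounter_id", "patient_id", "event_time", "kind",
                  "cpt_codes")
)

TIME_COLUMNS <- c(admissions = NA, labs = "collected_time",
                  cultures = "collected_time", flowsheets = "observed_time",
                  medications = "event_time", procedures = "event_time")

RACE_LEVELS <- c("Asian/Pacific Islander", "Black", "Caucasian-Hispanic",
                 "Caucasian-Non-Hispanic", "Other-Hispanic",
                 "Other-Non-Hispanic")

#' @keywords internal
#' @noRd
empty_table <- function(table) {
  cols <- COHORT_SCHEMA[[table]]
  df <- as.data.frame(
    stats::setNames(replicate(length(cols), character(0), simplify = FALSE), cols),
    stringsAsFactors = FALSE)
  coerce_table(df, table)
}

#' @keywords internal
#' @noRd
coerce_table <- function(df, table) {
  num_cols <- c("age_years", "numeric_value", "colony_count", "value_num")
  lgl_cols <- c("died_inpatient", "positive")
  tcol <- TIME_COLUMNS[[table]]
  for (cl in intersect(c("admit_time", "discharge_time", tcol),
                       names(df))) {
    if (!inherits(df[[cl]], "POSIXct") && !is.numeric(df[[cl]])) {
      df[[cl]] <- parse_time(df[[cl]], table, cl)
    }
  }
  for (cl in intersect(num_cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in intersect(lgl_cols, names(df))) {
    if (!is.logical(df[[cl]])) df[[cl]] <- as.logical(toupper(as.character(df[[cl]])))
  }
  chr_cols <- setdiff(names(df), c(num_cols, lgl_cols, "admit_time",
                                   "discharge_time", tcol))
  for (cl in chr_cols) df[[cl]] <- as.character(df[[cl]])
  if (table == "admissions" && nrow(df)) {
    df$billed_icd_codes <- join_icd_list(split_icd_list(df$billed_icd_codes))
  }
  rownames(df) <- NULL
  df
}

#' Assemble an EHR cohort object
#'
#' A cohort bundles the six delimited extract tables into one validated
#' container. Each clinical record links to its hospitalization encounter by
#' `encounter_id`; records from lookback sources (echocardiography, BNP,
#' problem list, HIV screens, transplant history) may instead carry only a
#' `patient_id` when they predate the index encounter.
#'
#' @param admissions data frame of hospitalization encounters, one row per
#'   admission (`encounter_id`, `patient_id`, `admit_time`, `discharge_time`,
#'   `died_inpatient`, `raw_financial_class`, `sex`, `race_ethnicity`,
#'   `age_years`, `billed_icd_codes` as a `;`-separated ICD-10 list,
#'   `billed_drg_code`).
#' @param labs,cultures,flowsheets,medications,procedures clinical source
#'   tables; missing tables default to empty.
#' @return an object of class `ehr_cohort`
#' @seealso [read_cohort()], [validate_cohort()], [generate_cohort()]
#' @export
ehr_cohort <- function(admissions = NULL, labs = NULL, cultures = NULL,
                       flowsheets = NULL, medications = NULL,
                       procedures = NULL) {
  tabs <- list(admissions = admissions, labs = labs, cultures = cultures,
               flowsheets = flowsheets, medications = medications,
               procedures = procedures)
  out <- lapply(names(tabs), function(nm) {
    df <- tabs[[nm]]
    if (is.null(df)) return(empty_table(nm))
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    missing_cols <- setdiff(COHORT_SCHEMA[[nm]], names(df))
    for (cl in missing_cols) df[[cl]] <- NA
    coerce_table(df[COHORT_SCHEMA[[nm]]], nm)
  })
  names(out) <- names(tabs)
  structure(out, class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>\n")
  for (nm in names(COHORT_SCHEMA)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Read a cohort from a directory of delimited files
#'
#' Expects one comma-delimited UTF-8 file per table
#' (`admissions.csv`, `labs.csv`, `cultures.csv`, `flowsheets.csv`,
#' `medications.csv`, `procedures.csv`) with a header row and ISO-8601
#' timestamps (or bare numeric day offsets for de-identified cohorts).
#' Unknown columns are dropped with a warning; a missing file or a missing
#' required column is a fatal schema error naming the file and column.
#'
#' @param directory_path directory holding the six CSV files
#' @param schema_config optional column-name remapping for foreign extracts:
#'   a nested list (or path to a YAML file) of the form
#'   `list(labs = c(collected_time = "RESULT_DTTM"), ...)` mapping canonical
#'   column names to the names used in the files.
#' @return an `ehr_cohort`
#' @export
read_cohort <- function(directory_path, schema_config = NULL) {
  if (is.character(schema_config) && length(schema_config) == 1) {
    schema_config <- yaml::read_yaml(schema_config)
  }
  tabs <- list()
  for (nm in names(COHORT_SCHEMA)) {
    path <- file.path(directory_path, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("missing required file '%s.csv' in %s", nm, directory_path),
           call. = FALSE)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    remap <- schema_config[[nm]]
    if (!is.null(remap)) {
      for (canon in names(remap)) {
        if (remap[[canon]] %in% names(df)) {
          names(df)[names(df) == remap[[canon]]] <- canon
        }
      }
    }
    extra <- setdiff(names(df), COHORT_SCHEMA[[nm]])
    if (length(extra)) {
      warning(sprintf("ignoring unknown column(s) in %s.csv: %s", nm,
                      paste(extra, collapse = ", ")), call. = FALSE)
      df <- df[setdiff(names(df), extra)]
    }
    miss <- setdiff(COHORT_SCHEMA[[nm]], names(df))
    if (length(miss)) {
      stop(sprintf("file '%s.csv' is missing required column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    # blanks become NA in optional fields and unlinked id columns
    for (cl in c("billed_drg_code", "abnormal_flag", "value_chr", "cpt_codes",
                 "encounter_id", "patient_id")) {
      if (cl %in% names(df)) df[[cl]][!nzchar(df[[cl]])] <- NA
    }
    for (cl in c("numeric_value", "colony_count", "value_num", "age_years")) {
      if (cl %in% names(df)) df[[cl]][!nzchar(df[[cl]])] <- NA
    }
    tabs[[nm]] <- df
  }
  do.call(ehr_cohort, tabs)
}

#' Write a cohort to a directory of delimited files
#'
#' Emits the six CSV tables in the dialect [read_cohort()] reads back
#' losslessly (ISO-8601 timestamps at second resolution, or plain numeric
#' day offsets for de-identified cohorts). No identifier columns beyond the
#' opaque `encounter_id`/`patient_id` keys are ever written.
#'
#' @param cohort an `ehr_cohort`
#' @param directory_path output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, directory_path) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(COHORT_SCHEMA)) {
    df <- cohort[[nm]]
    tcols <- intersect(c("admit_time", "discharge_time", TIME_COLUMNS[[nm]]),
                       names(df))
    for (cl in tcols) df[[cl]] <- ifelse(is.na(df[[cl]]), "", fmt_time(df[[cl]]))
    for (cl in names(df)) {
      if (is.logical(df[[cl]])) df[[cl]] <- ifelse(is.na(df[[cl]]), "", df[[cl]])
    }
    path <- file.path(directory_path, paste0(nm, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @keywords internal
#' @noRd
violation <- function(table, row, rule, message) {
  data.frame(table = table, row = row, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Check a cohort against its structural invariants
#'
#' Validation never throws: every violation is returned as one row of a
#' descriptor data frame (empty when the cohort is valid). Checked
#' invariants: unique encounter ids; `admit_time <= discharge_time`;
#' duplicate-free billed ICD lists; clinical values within physiologic
#' ranges (GCS 3-15, BMI > 0, ejection fraction in (0, 100]); colony counts
#' only on urine specimens and non-negative; lab rows carrying a numeric
#' value or an abnormal flag; non-empty drug names; and referential
#' integrity -- every child record must resolve to an admission by
#' `encounter_id` or to a known patient by `patient_id`.
#'
#' @param cohort an `ehr_cohort`
#' @return data frame with columns `table`, `row`, `rule`, `message`;
#'   zero rows iff the cohort is valid
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  out <- list()
  adm <- cohort$admissions
  if (nrow(adm)) {
    dup <- which(duplicated(adm$encounter_id))
    for (i in dup) out[[length(out) + 1]] <-
      violation("admissions", i, "unique_encounter",
                sprintf("duplicate encounter_id '%s'", adm$encounter_id[i]))
    bad <- which(!is.na(adm$admit_time) & !is.na(adm$discharge_time) &
                   as_days(adm$admit_time) > as_days(adm$discharge_time))
    for (i in bad) out[[length(out) + 1]] <-
      violation("admissions", i, "time_ordering",
                sprintf("encounter '%s' discharged before admission",
                        adm$encounter_id[i]))
    bad <- which(!is.na(adm$age_years) & adm$age_years < 0)
    for (i in bad) out[[length(out) + 1]] <-
      violation("admissions", i, "age_nonnegative", "negative age_years")
  }
  known_enc <- adm$encounter_id
  known_pat <- adm$patient_id
  for (nm in setdiff(names(COHORT_SCHEMA), "admissions")) {
    df <- cohort[[nm]]
    if (!nrow(df)) next
    enc_ok <- !is.na(df$encounter_id) & nzchar(df$encounter_id) &
      df$encounter_id %in% known_enc
    pat_ok <- if ("patient_id" %in% names(df)) {
      !is.na(df$patient_id) & nzchar(df$patient_id) & df$patient_id %in% known_pat
    } else rep(FALSE, nrow(df))
    for (i in which(!enc_ok & !pat_ok)) out[[length(out) + 1]] <-
      violation(nm, i, "dangling_reference",
                "record resolves to no admission or known patient")
  }
  labs <- cohort$labs
  for (i in which(is.na(labs$numeric_value) &
                  (is.na(labs$abnormal_flag) | !nzchar(labs$abnormal_flag)))) {
    out[[length(out) + 1]] <-
      violation("labs", i, "value_or_flag",
                "lab row has neither numeric_value nor abnormal_flag")
  }
  cul <- cohort$cultures
  for (i in which(!is.na(cul$colony_count) & cul$specimen != "urine")) {
    out[[length(out) + 1]] <-
      violation("cultures", i, "colony_urine_only",
                "colony_count on a non-urine specimen")
  }
  for (i in which(!is.na(cul$colony_count) & cul$colony_count < 0)) {
    out[[length(out) + 1]] <-
      violation("cultures", i, "colony_nonnegative", "negative colony_count")
  }
  fs <- cohort$flowsheets
  rng <- list(GCS_total = c(3, 15), BMI = c(1e-9, Inf),
              ejection_fraction = c(1e-9, 100))
  for (ms in names(rng)) {
    i_bad <- which(fs$measure == ms & !is.na(fs$value_num) &
                     (fs$value_num < rng[[ms]][1] | fs$value_num > rng[[ms]][2]))
    for (i in i_bad) out[[length(out) + 1]] <-
      violation("flowsheets", i, paste0(ms, "_range"),
                sprintf("%s value %g out of range", ms, fs$value_num[i]))
  }
  med <- cohort$medications
  for (i in which(is.na(med$drug) | !nzchar(med$drug))) {
    out[[length(out) + 1]] <- violation("medications", i, "drug_nonempty",
                                        "empty drug name")
  }
  if (!length(out)) {
    return(violation("x", 1L, "x", "x")[0, ])
  }
  do.call(rbind, out)
}

#' @keywords internal
#' @noRd
hash_id <- function(salt, ids) {
  vapply(ids, function(id) {
    if (is.na(id) || !nzchar(id)) return(NA_character_)
    substr(digest::digest(paste0(salt, "|", id), algo = "sha256",
                          serialize = FALSE), 1, 16)
  }, character(1), USE.NAMES = FALSE)
}

#' De-identify a cohort
#'
#' Patient and encounter identifiers are replaced by salted one-way SHA-256
#' hashes (the salt is combined with each identifier, so the mapping is
#' keyed per patient yet reproducible within a call), and every timestamp is
#' replaced by its offset in fractional days from that patient's earliest
#' recorded event. Relative orderings, all inter-event intervals, and all
#' join relationships are preserved exactly; two calls with different salts
#' yield disjoint identifier sets but identical offsets.
#'
#' @param cohort an `ehr_cohort`
#' @param salt non-empty character scalar
#' @return a de-identified `ehr_cohort` (timestamps become numeric day
#'   offsets)
#' @export
deidentify <- function(cohort, salt) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!is.character(salt) || length(salt) != 1 || is.na(salt) || !nzchar(salt)) {
    stop("salt must be a non-empty string", call. = FALSE)
  }
  adm <- cohort$admissions
  enc2pat <- stats::setNames(adm$patient_id, adm$encounter_id)

  # earliest event per patient, pooled across all tables
  all_pats <- adm$patient_id
  all_times <- as_days(adm$admit_time)
  for (nm in setdiff(names(COHORT_SCHEMA), "admissions")) {
    df <- cohort[[nm]]
    if (!nrow(df)) next
    pat <- if ("patient_id" %in% names(df)) df$patient_id else rep(NA_character_, nrow(df))
    pat <- ifelse(is.na(pat) | !nzchar(pat),
                  unname(enc2pat[df$encounter_id]), pat)
    all_pats <- c(all_pats, pat)
    all_times <- c(all_times, as_days(df[[TIME_COLUMNS[[nm]]]]))
  }
  ok <- !is.na(all_pats) & !is.na(all_times)
  first_day <- tapply(all_times[ok], all_pats[ok], min)

  rel <- function(times, pats) {
    as.vector(as_days(times) - unname(first_day[pats]))
  }
  out <- cohort
  pat_adm <- adm$patient_id
  out$admissions$admit_time <- rel(adm$admit_time, pat_adm)
  out$admissions$discharge_time <- rel(adm$discharge_time, pat_adm)
  out$admissions$encounter_id <- hash_id(salt, adm$encounter_id)
  out$admissions$patient_id <- hash_id(salt, adm$patient_id)
  for (nm in setdiff(names(COHORT_SCHEMA), "admissions")) {
    df <- cohort[[nm]]
    if (!nrow(df)) {
      tcl <- TIME_COLUMNS[[nm]]
      out[[nm]][[tcl]] <- numeric(0)
      next
    }
    pat <- if ("patient_id" %in% names(df)) df$patient_id else rep(NA_character_, nrow(df))
    pat <- ifelse(is.na(pat) | !nzchar(pat), unname(enc2pat[df$encounter_id]), pat)
    tcl <- TIME_COLUMNS[[nm]]
    out[[nm]][[tcl]] <- rel(df[[tcl]], pat)
    out[[nm]]$encounter_id <- hash_id(salt, df$encounter_id)
    if ("patient_id" %in% names(df)) {
      out[[nm]]$patient_id <- hash_id(salt, df$patient_id)
    }
  }
  out
}
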