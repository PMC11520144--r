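# ICD-10 wildcard matching, omission flagging, DRG severity-tier parsing
# (Base / CC / MCC / Singlet plus CC/MCC doublet arms), and DRG upgrade
# eligibility. The severity ladder is BASE < CC < MCC; Singlet DRGs have no
# tiered siblings and are never considered for modification.

# numeric severity used when comparing a *billed* level against the level a
# detected disease requires; a CC/MCC doublet arm is CC-satisfying
LEVEL_BILLED_VALUE <- c(BASE = 0, CC = 1, "CC/MCC" = 1, MCC = 2)
# numeric severity an entry *provides* when chosen as an upgrade target; a
# CC/MCC doublet arm is MCC-satisfying
LEVEL_TARGET_VALUE <- c(CC = 1, "CC/MCC" = 2, MCC = 2)
UPGRADE_TYPES <- c("none", "base_to_CC", "base_to_MCC", "CC_to_MCC")

#' @keywords internal
#' @noRd
parse_icd_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || is.na(pattern) ||
      !nzchar(pattern)) {
    stop("ICD pattern must be a non-empty string", call. = FALSE)
  }
  p <- normalize_icd(pattern)
  n_star <- lengths(regmatches(p, gregexpr("\\*", p)))
  if (n_star > 1 || (n_star == 1 && !grepl("(\\.\\*|\\*)$", p))) {
    stop(sprintf("malformed ICD pattern '%s': at most one trailing '.*' or '*'",
                 pattern), call. = FALSE)
  }
  if (grepl("(\\.\\*|\\*)$", p)) {
    list(root = sub("\\.?\\*$", "", p), wildcard = TRUE)
  } else {
    list(root = p, wildcard = FALSE)
  }
}

#' Match an ICD-10 code against a literal or prefix-wildcard pattern
#'
#' Literal patterns match exactly. A wildcard pattern `"X.*"` matches the
#' root `"X"` itself and any code extending `"X."`, but never a sibling
#' root: `"K85.*"` matches `"K85"` and `"K85.90"` but not `"K851"`. By
#' default the root itself counts (the audit asks whether any clinically
#' relevant code is present); set `include_root = FALSE` for children-only
#' semantics. Malformed patterns error here and at rulebook load.
#'
#' @param pattern literal code (`"E87.1"`) or prefix wildcard (`"I50.*"`)
#' @param code character vector of normalized (uppercase, trimmed) codes
#' @param include_root should a wildcard match its bare root code?
#' @return logical vector, one element per code
#' @export
match_icd <- function(pattern, code, include_root = TRUE) {
  p <- parse_icd_pattern(pattern)
  code <- normalize_icd(code)
  if (!p$wildcard) return(code == p$root)
  hit <- startsWith(code, paste0(p$root, "."))
  if (include_root) hit <- hit | code == p$root
  hit
}

#' @keywords internal
#' @noRd
any_icd_match <- function(patterns, codes) {
  if (!length(patterns) || !length(codes)) return(FALSE)
  any(vapply(patterns, function(p) any(match_icd(p, codes)), logical(1)))
}

# fast path over pre-parsed patterns and pre-normalized codes
#' @keywords internal
#' @noRd
any_icd_match_parsed <- function(parsed, codes) {
  if (!length(parsed) || !length(codes)) return(FALSE)
  for (p in parsed) {
    if (p$wildcard) {
      if (any(codes == p$root | startsWith(codes, paste0(p$root, "."))))
        return(TRUE)
    } else if (any(codes == p$root)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Flag an admission as missing applicable ICD data for one disease
#'
#' An admission with clinical evidence of a disease (per its phenotype call)
#' whose billed code list contains none of the disease's qualifying ICD
#' codes is flagged as missing applicable ICD data. Diseases with an empty
#' qualifying list (Inpatient Death) are never flagged. The converse cell --
#' a qualifying code present without clinical evidence -- is retained as
#' `icd_present` with `detected = FALSE` (the "algorithm not sensitive"
#' column of the per-disease audit table).
#'
#' @param call a `phenotype_call` (or any list with `encounter_id`,
#'   `disease_name`, `detected`)
#' @param admission one-row slice of the admissions table sharing the call's
#'   `encounter_id`
#' @param rule the `phenotype_rule` for the same disease
#' @return one-row data frame: `encounter_id`, `disease_name`, `detected`,
#'   `icd_present`, `missing_icd`
#' @export
flag_missing_icd <- function(call, admission, rule) {
  stopifnot(call$encounter_id == admission$encounter_id,
            call$disease_name == rule$disease_name)
  codes <- split_icd_list(admission$billed_icd_codes)[[1]]
  present <- any_icd_match(rule$qualifying_icd_patterns, codes)
  data.frame(encounter_id = call$encounter_id,
             disease_name = call$disease_name,
             detected = isTRUE(call$detected),
             icd_present = present,
             missing_icd = isTRUE(call$detected) && !present &&
               length(rule$qualifying_icd_patterns) > 0,
             stringsAsFactors = FALSE)
}

#' Audit every phenotype call for ICD omissions
#'
#' Vectorized form of [flag_missing_icd()]: one finding per admission x
#' disease. Admissions with no billed codes at all are still audited
#' (`icd_present = FALSE` everywhere).
#'
#' @param calls output of [evaluate_cohort()]
#' @param cohort the matching `ehr_cohort`
#' @param rulebook the `phenotype_rulebook` the calls came from
#' @return data frame of findings: `encounter_id`, `disease_name`,
#'   `detected`, `icd_present`, `missing_icd`
#' @export
audit_findings <- function(calls, cohort, rulebook) {
  adm <- cohort$admissions
  if (!nrow(adm)) {
    return(data.frame(encounter_id = character(0), disease_name = character(0),
                      detected = logical(0), icd_present = logical(0),
                      missing_icd = logical(0), stringsAsFactors = FALSE))
  }
  code_list <- split_icd_list(adm$billed_icd_codes)
  present_mat <- vapply(rulebook, function(rule) {
    parsed <- lapply(rule$qualifying_icd_patterns, parse_icd_pattern)
    vapply(code_list, function(codes) any_icd_match_parsed(parsed, codes),
           logical(1))
  }, logical(max(1, nrow(adm))))
  if (nrow(adm) == 1) present_mat <- matrix(present_mat, nrow = 1,
                                            dimnames = list(NULL, names(rulebook)))
  i <- match(calls$encounter_id, adm$encounter_id)
  present <- present_mat[cbind(i, match(calls$disease_name,
                                        colnames(present_mat)))]
  has_patterns <- lengths(lapply(rulebook, `[[`, "qualifying_icd_patterns")) > 0
  data.frame(encounter_id = calls$encounter_id,
             disease_name = calls$disease_name,
             detected = calls$detected,
             icd_present = unname(present),
             missing_icd = calls$detected & !present &
               unname(has_patterns[calls$disease_name]),
             stringsAsFactors = FALSE)
}

# ---- DRG catalogue ----------------------------------------------------------

#' Parse the severity suffix of a DRG text description
#'
#' Case-insensitive suffix grammar over CMS-style descriptions:
#' `"... WITH MCC"` is MCC, `"... WITH CC"` is CC, `"... WITH CC/MCC"` is
#' the doublet arm `"CC/MCC"`, and any `"... WITHOUT CC/MCC"` /
#' `"... WITHOUT MCC"` / `"... WITHOUT CC"` arm is BASE. A description with
#' no recognized suffix is SINGLET at this stage; the family-level pass in
#' [load_drg_catalogue()] reassigns it to BASE when tiered siblings exist
#' (a lone description with no leveled siblings stays SINGLET).
#'
#' @param description DRG text description(s)
#' @return character vector of levels: `"MCC"`, `"CC"`, `"CC/MCC"`,
#'   `"BASE"`, or `"SINGLET"`
#' @examples
#' classify_drg("PLEURAL EFFUSION WITH MCC")
#' classify_drg("PLEURAL EFFUSION WITHOUT CC/MCC")
#' @export
classify_drg <- function(description) {
  d <- toupper(trimws(description))
  d <- sub("[[:space:][:punct:]]+$", "", d)
  out <- rep("SINGLET", length(d))
  # the four suffix patterns are mutually exclusive as anchored regexes
  out[grepl("WITH MCC$", d)] <- "MCC"
  out[grepl("WITH CC$", d)] <- "CC"
  out[grepl("WITH CC/MCC$", d)] <- "CC/MCC"
  out[grepl("WITHOUT (CC/MCC|MCC OR CC|MCC|CC)$", d)] <- "BASE"
  out
}

#' Strip the severity-modifier suffix from a DRG description
#'
#' Removes the recognized level suffixes and trailing whitespace or
#' punctuation so all tier arms of one diagnosis group collapse to a single
#' family string. Idempotent.
#'
#' @param description DRG text description(s)
#' @return the modifier-stripped family string(s)
#' @examples
#' strip_family("PLEURAL EFFUSION WITH CC")  # "PLEURAL EFFUSION"
#' @export
strip_family <- function(description) {
  d <- toupper(trimws(description))
  d <- sub("[[:space:][:punct:]]+$", "", d)
  d <- sub("\\s*(WITH|WITHOUT)\\s+(CC/MCC|MCC OR CC|MCC|CC)$", "", d)
  sub("[[:space:][:punct:]]+$", "", d)
}

#' Load and classify a DRG catalogue
#'
#' Reads a CSV mirroring the CMS download -- columns `drg_code`,
#' `description`, `rwf` (relative weighting factor) -- then derives each
#' entry's severity level and modifier-stripped family, applying the
#' family-level pass that distinguishes BASE from SINGLET descriptions.
#'
#' @param path CSV file path, or a data frame with the same three columns
#' @return a `drg_catalogue` data frame: `drg_code`, `description`,
#'   `level`, `family`, `rwf`
#' @export
load_drg_catalogue <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drg_code", "description", "rwf")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("DRG catalogue is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$drg_code <- as.character(df$drg_code)
  df$rwf <- as.numeric(df$rwf)
  if (anyDuplicated(df$drg_code)) {
    stop("duplicate drg_code in catalogue", call. = FALSE)
  }
  if (any(is.na(df$rwf))) stop("missing rwf in catalogue", call. = FALSE)
  if (any(df$rwf <= 0)) stop("rwf must be positive", call. = FALSE)
  df$level <- classify_drg(df$description)
  df$family <- strip_family(df$description)
  # family pass: an unleveled description with leveled siblings is BASE
  leveled_fams <- unique(df$family[df$level != "SINGLET"])
  df$level[df$level == "SINGLET" & df$family %in% leveled_fams] <- "BASE"
  out <- df[, c("drg_code", "description", "level", "family", "rwf")]
  class(out) <- c("drg_catalogue", "data.frame")
  out
}

#' Evaluate DRG upgrade eligibility for one admission
#'
#' The level required by the clinical picture is the highest modifier level
#' over the admission's detected diseases (one flag per admission at most --
#' redundancy across diseases is eliminated by taking the maximum). A
#' Singlet billed DRG is never considered for modification. Otherwise, if
#' the required level exceeds the billed level, the proposed target is the
#' catalogue entry in the billed DRG's own family at the required level;
#' when the family lacks that level the highest level the family offers
#' above the billed one is used, and when none exists the flag is `"none"`.
#' `delta_rwf` is the target-minus-billed weighting-factor difference,
#' floored at zero.
#'
#' @param detected data frame of the admission's detected diseases with
#'   columns `disease_name` and `modifier_level` (`"CC"`/`"MCC"`), e.g. the
#'   detected rows of [evaluate_cohort()] for one encounter
#' @param billed_drg_entry one-row slice of a `drg_catalogue` for the billed
#'   DRG
#' @param catalogue the full `drg_catalogue`
#' @return a one-row data frame (`upgrade_flag`): `upgrade_type`,
#'   `billed_drg`, `billed_level`, `target_drg`, `target_level`,
#'   `delta_rwf`, `driving_diseases` (`;`-joined)
#' @export
evaluate_upgrade <- function(detected, billed_drg_entry, catalogue) {
  none <- data.frame(upgrade_type = "none",
                     billed_drg = billed_drg_entry$drg_code,
                     billed_level = billed_drg_entry$level,
                     target_drg = NA_character_, target_level = NA_character_,
                     delta_rwf = 0, driving_diseases = "",
                     stringsAsFactors = FALSE)
  if (billed_drg_entry$level == "SINGLET") return(none)
  if (!nrow(detected)) return(none)
  req <- max(ifelse(detected$modifier_level == "MCC", 2L, 1L))
  billed_val <- unname(LEVEL_BILLED_VALUE[billed_drg_entry$level])
  if (req <= billed_val) return(none)
  fam <- catalogue[catalogue$family == billed_drg_entry$family &
                     catalogue$level %in% names(LEVEL_TARGET_VALUE), , drop = FALSE]
  fam$tval <- unname(LEVEL_TARGET_VALUE[fam$level])
  cand <- fam[fam$tval > billed_val & fam$tval <= req, , drop = FALSE]
  if (!nrow(cand)) return(none)
  # highest achievable level; prefer a plain-tier entry over a doublet arm
  best_val <- max(cand$tval)
  cand <- cand[cand$tval == best_val, , drop = FALSE]
  target <- cand[order(nchar(cand$level), cand$drg_code), , drop = FALSE][1, ]
  type <- if (billed_val == 0 && best_val == 1) "base_to_CC"
  else if (billed_val == 0 && best_val == 2) "base_to_MCC"
  else "CC_to_MCC"
  driving <- detected$disease_name[
    ifelse(detected$modifier_level == "MCC", 2L, 1L) > billed_val]
  data.frame(upgrade_type = type, billed_drg = billed_drg_entry$drg_code,
             billed_level = billed_drg_entry$level,
             target_drg = target$drg_code, target_level = target$level,
             delta_rwf = max(0, target$rwf - billed_drg_entry$rwf),
             driving_diseases = paste(sort(driving), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Evaluate DRG upgrades for every admission in a cohort
#'
#' Applies [evaluate_upgrade()] per admission. Admissions whose billed DRG
#' is absent (or not found in the catalogue) are excluded and reported via a
#' warning, mirroring an audit's exclusion of encounters without an
#' established DRG.
#'
#' @param calls output of [evaluate_cohort()]
#' @param cohort the matching `ehr_cohort`
#' @param catalogue a `drg_catalogue`
#' @return data frame with one row per auditable admission: `encounter_id`
#'   plus the [evaluate_upgrade()] columns
#' @export
evaluate_upgrades <- function(calls, cohort, catalogue) {
  adm <- cohort$admissions
  m <- match(adm$billed_drg_code, catalogue$drg_code)
  skipped <- is.na(adm$billed_drg_code) | is.na(m)
  if (any(skipped)) {
    warning(sprintf("%d admission(s) without a catalogued billed DRG were excluded from upgrade evaluation",
                    sum(skipped)), call. = FALSE)
  }
  det <- calls[calls$detected, c("encounter_id", "disease_name",
                                 "modifier_level"), drop = FALSE]
  det_by_enc <- split(det, det$encounter_id)
  empty_det <- det[0, , drop = FALSE]
  rows <- lapply(which(!skipped), function(i) {
    d <- det_by_enc[[adm$encounter_id[i]]] %||% empty_det
    flag <- evaluate_upgrade(d, catalogue[m[i], , drop = FALSE], catalogue)
    cbind(data.frame(encounter_id = adm$encounter_id[i],
                     stringsAsFactors = FALSE), flag)
  })
  if (!length(rows)) {
    return(data.frame(encounter_id = character(0), upgrade_type = character(0),
                      billed_drg = character(0), billed_level = character(0),
                      target_drg = character(0), target_level = character(0),
                      delta_rwf = numeric(0), driving_diseases = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
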