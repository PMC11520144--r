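# Pipeline orchestration: cohort ingestion -> phenotyping -> ICD/DRG audit
# -> revenue valuation -> cohort statistics -> report bundle.

#' Run the full coding audit over a cohort
#'
#' Wires every stage together: phenotype evaluation of the nineteen disease
#' algorithms, per-disease ICD-omission findings, DRG upgrade flags with
#' payor grouping, the payor-stratified revenue summary, the per-disease
#' audit table, the demographic balance table, and the ICD-limit census.
#' Deterministic for a fixed cohort and configuration. When `out_dir` is
#' given the report bundle is also written via [write_reports()].
#'
#' @param cohort an `ehr_cohort`, or a directory path for [read_cohort()]
#' @param catalogue a `drg_catalogue`, or a CSV path for
#'   [load_drg_catalogue()]
#' @param rulebook a `phenotype_rulebook` (default [build_rulebook()]), or
#'   a YAML threshold file
#' @param rates dollars-per-RWF schedule ([default_rate_schedule()]), or a
#'   YAML file of `payor: dollars` pairs
#' @param payor_mapping raw-financial-class mapping
#'   ([default_payor_mapping()]) or a YAML file
#' @param ci_level confidence level for incidence intervals
#' @param icd_limit payor ICD code-count limit for the census
#' @param seed recorded in the manifest (the audit itself is deterministic)
#' @param out_dir optional report output directory
#' @param validate stop when [validate_cohort()] reports violations?
#' @return a `drg_audit` object: list with `calls`, `findings`, `upgrades`
#'   (with `payor` and `lost_revenue` columns), `revenue`, `audit_table`,
#'   `balance`, `icd_census`, `upgrade_counts`, `incidence`, and `manifest`
#' @export
run_audit <- function(cohort, catalogue, rulebook = build_rulebook(),
                      rates = default_rate_schedule(),
                      payor_mapping = default_payor_mapping(),
                      ci_level = 0.95, icd_limit = 25, seed = NULL,
                      out_dir = NULL, validate = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(catalogue, "drg_catalogue")) {
    catalogue <- load_drg_catalogue(catalogue)
  }
  if (!inherits(rulebook, "phenotype_rulebook")) {
    rulebook <- build_rulebook(rulebook)
  }
  if (is.character(rates)) rates <- unlist(yaml::read_yaml(rates))
  if (validate) {
    v <- validate_cohort(cohort)
    if (nrow(v)) {
      stop(sprintf("cohort failed validation with %d violation(s); first: [%s row %d] %s",
                   nrow(v), v$table[1], v$row[1], v$message[1]), call. = FALSE)
    }
  }
  calls <- evaluate_cohort(rulebook, cohort)
  findings <- audit_findings(calls, cohort, rulebook)
  upgrades <- evaluate_upgrades(calls, cohort, catalogue)
  adm <- cohort$admissions
  payor <- group_payor(adm$raw_financial_class, payor_mapping)
  upgrades$payor <- payor[match(upgrades$encounter_id, adm$encounter_id)]
  upgrades$lost_revenue <- ifelse(
    upgrades$upgrade_type == "none", 0,
    round_half_up(upgrades$delta_rwf *
                    unname(rates[upgrades$payor]), 2))
  revenue <- summarize_revenue(upgrades, rates)
  atab <- build_audit_table(findings, upgrades)
  bal <- balance_table(cohort, findings, payor_mapping = payor_mapping)
  census <- icd_limit_census(cohort, upgrades, limit = icd_limit,
                             payor_mapping = payor_mapping)
  counts <- table(factor(upgrades$upgrade_type,
                         levels = setdiff(UPGRADE_TYPES, "none")))
  upgrade_counts <- c(as.list(counts),
                      list(total = sum(counts)))
  n_adm <- nrow(adm)
  missing_any <- length(unique(findings$encounter_id[findings$missing_icd]))
  incidence <- list(
    missing_any_icd = incidence_with_ci(missing_any, n_adm, ci_level),
    upgrade_eligible = incidence_with_ci(sum(upgrades$upgrade_type != "none"),
                                         max(1, nrow(upgrades)), ci_level))
  manifest <- list(
    package_version = as.character(utils::packageVersion("drgaudit")),
    seed = seed, n_admissions = n_adm, ci_level = ci_level,
    icd_limit = icd_limit,
    rates = as.list(rates[PAYOR_CLASSES]),
    config_hash = digest::digest(list(ci_level, icd_limit,
                                      rates[PAYOR_CLASSES],
                                      attr(rulebook, "thresholds"))))
  res <- structure(list(calls = calls, findings = findings,
                        upgrades = upgrades, revenue = revenue,
                        audit_table = atab, balance = bal,
                        icd_census = census, upgrade_counts = upgrade_counts,
                        incidence = incidence, manifest = manifest),
                   class = "drg_audit")
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

#' @export
print.drg_audit <- function(x, ...) {
  n <- x$manifest$n_admissions
  cat(sprintf("<drg_audit> %d admissions audited against %d disease algorithms\n",
              n, length(unique(x$findings$disease_name))))
  est <- x$incidence$missing_any_icd
  cat(sprintf("  admissions missing >=1 qualifying ICD code: %d (%.1f%%, %d%% CI %.1f-%.1f%%)\n",
              est$k, 100 * est$proportion, round(100 * est$level),
              100 * est$ci_low, 100 * est$ci_high))
  uc <- x$upgrade_counts
  cat(sprintf("  DRG upgrade eligible: %d (base->CC %d, base->MCC %d, CC->MCC %d)\n",
              uc$total, uc$base_to_CC, uc$base_to_MCC, uc$CC_to_MCC))
  cat(sprintf("  estimated lost revenue: $%s\n",
              formatC(x$revenue$grand_total, format = "f", digits = 2,
                      big.mark = ",")))
  invisible(x)
}

#' @export
summary.drg_audit <- function(object, ...) {
  print(object)
  cat("\nPer-disease audit table:\n")
  print(as.data.frame(object$audit_table), row.names = FALSE)
  cat("\nRevenue summary:\n")
  print(object$revenue)
  cat("\nDemographic balance (accurate vs unbilled coding):\n")
  print(object$balance, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Write the audit report bundle
#'
#' Emits `audit_table.csv`, `revenue_table.csv`, `balance_table.csv`,
#' `upgrade_counts.json` and `manifest.json`. Byte-identical across runs
#' with the same cohort and configuration.
#'
#' @param audit a `drg_audit`
#' @param out_dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_reports <- function(audit, out_dir) {
  stopifnot(inherits(audit, "drg_audit"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- character(0)
  f <- file.path(out_dir, "audit_table.csv")
  utils::write.csv(as.data.frame(audit$audit_table), f, row.names = FALSE,
                   na = "")
  p <- c(p, f)
  f <- file.path(out_dir, "revenue_table.csv")
  utils::write.csv(audit$revenue$lines, f, row.names = FALSE, na = "")
  p <- c(p, f)
  f <- file.path(out_dir, "balance_table.csv")
  utils::write.csv(audit$balance, f, row.names = FALSE, na = "")
  p <- c(p, f)
  f <- file.path(out_dir, "upgrade_counts.json")
  jsonlite::write_json(audit$upgrade_counts, f, auto_unbox = TRUE)
  p <- c(p, f)
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(audit$manifest, f, auto_unbox = TRUE, null = "null")
  p <- c(p, f)
  invisible(p)
}

#' Generate the demonstration fixture set
#'
#' Writes a seeded synthetic cohort (default n = 500) as the six CSV
#' tables, the latent truth as `truth.csv`, and a copy of the synthetic
#' DRG mini-catalogue, so the full pipeline can be exercised from files.
#'
#' @param out_dir output directory
#' @param seed generator seed
#' @param n_admissions cohort size
#' @return invisibly, the [generate_cohort()] result
#' @export
make_fixtures <- function(out_dir, seed = 1, n_admissions = 500) {
  gen <- generate_cohort(synth_config(n_admissions = n_admissions,
                                      seed = seed))
  write_cohort(gen$cohort, out_dir)
  truth_adm <- gen$truth$admissions
  utils::write.csv(truth_adm, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(gen$truth$diseases,
                   file.path(out_dir, "truth_diseases.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(synthetic_drg_catalogue())[
    , c("drg_code", "description", "rwf")],
    file.path(out_dir, "drg_catalogue.csv"), row.names = FALSE)
  invisible(gen)
}
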