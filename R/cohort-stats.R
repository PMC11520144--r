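# Incidence estimates with exact binomial confidence intervals, covariate
# balance between accurately-coded and unbilled admissions (standardized
# mean differences plus reference-group tests), the payor ICD-limit census,
# and the per-disease audit summary table.

#' Incidence proportion with a binomial confidence interval
#'
#' Exact Clopper-Pearson interval by default (beta-quantile closed form,
#' identical to `stats::binom.test`); the Wilson score interval is
#' available behind `method = "wilson"`.
#'
#' @param k number of events (0 <= k <= n)
#' @param n denominator (> 0)
#' @param level confidence level, default 0.95
#' @param method `"clopper-pearson"` (default) or `"wilson"`
#' @return list of class `incidence_estimate`: `k`, `n`, `proportion`,
#'   `ci_low`, `ci_high`, `level`, `method`
#' @examples
#' incidence_with_ci(0, 10)  # upper bound 1 - 0.025^(1/10)
#' @export
incidence_with_ci <- function(k, n, level = 0.95,
                              method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n <= 0) stop("denominator n must be positive", call. = FALSE)
  stopifnot(k >= 0, k <= n)
  alpha <- 1 - level
  p <- k / n
  if (method == "clopper-pearson") {
    lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  structure(list(k = k, n = n, proportion = p, ci_low = lo, ci_high = hi,
                 level = level, method = method),
            class = "incidence_estimate")
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f%%-%.1f%%, %s)\n", x$k, x$n,
              100 * x$proportion, round(100 * x$level), 100 * x$ci_low,
              100 * x$ci_high, x$method))
  invisible(x)
}

#' Standardized mean difference for a binary variable
#'
#' `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)` with `p_i = k_i / n_i`.
#' Degenerate tables (both variances zero) return 0. Interpretation bands:
#' small 0-0.4, medium 0.4-0.6, large 0.6-1.0.
#'
#' @param k1,n1 events and total in group 1
#' @param k2,n2 events and total in group 2
#' @return non-negative SMD (symmetric in the two groups)
#' @examples
#' smd_binary(10739, 24621, 5385, 10361)  # 0.168
#' @export
smd_binary <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0)
  p1 <- k1 / n1; p2 <- k2 / n2
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v <= 0) return(0)
  abs(p1 - p2) / sqrt(v)
}

#' Standardized mean difference for a multi-category variable
#'
#' Mahalanobis-type generalization over the first K-1 category proportions:
#' `sqrt(t(T) S^-1 T)` where `T = p1 - p2` (last category dropped) and `S`
#' is the average of the two groups' multinomial covariance matrices --
#' the standard formulation in the covariate-balance literature. Categories
#' empty in both groups are dropped first; a two-category table reduces
#' exactly to [smd_binary()]. Invariant under permutation of category order.
#'
#' @param counts K x 2 matrix (or data frame) of category counts, one
#'   column per group
#' @return non-negative scalar SMD
#' @export
smd_multicategory <- function(counts) {
  m <- as.matrix(counts)
  stopifnot(ncol(m) == 2, all(colSums(m) > 0))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) return(0)
  p1 <- m[, 1] / sum(m[, 1]); p2 <- m[, 2] / sum(m[, 2])
  k <- nrow(m)
  T_ <- (p1 - p2)[-k]
  cov_of <- function(p) {
    S <- -outer(p[-k], p[-k]); diag(S) <- p[-k] * (1 - p[-k]); S
  }
  S <- (cov_of(p1) + cov_of(p2)) / 2
  Si <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  val <- drop(t(T_) %*% Si %*% T_)
  sqrt(max(0, val))
}

#' Compare one category to the reference category across coding-accuracy
#' groups
#'
#' Pearson chi-square (no continuity correction) on the 2x2 subtable of
#' counts for category `c` versus the reference category `r` across the two
#' groups; `method = "fisher"` switches to Fisher's exact test for small
#' tables. A zero margin yields p = 1 with a degenerate-table warning;
#' identical group proportions yield a zero statistic and p = 1.
#'
#' @param subtable 2x2 matrix: rows = (category, reference), columns = the
#'   two coding-accuracy groups
#' @param method `"chisq"` (default) or `"fisher"`
#' @return two-sided p-value in (0, 1]
#' @export
reference_group_test <- function(subtable, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  m <- as.matrix(subtable)
  stopifnot(all(dim(m) == c(2, 2)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1", call. = FALSE)
    return(1)
  }
  if (method == "fisher") return(stats::fisher.test(m)$p.value)
  p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  if (is.nan(p)) 1 else min(1, p)
}

#' Census of admissions at a payor's ICD code-count limit
#'
#' Counts admissions in the payor filter whose billed ICD list has reached
#' the submission limit, and the subset of those flagged for a DRG upgrade
#' (where a forced choice among codes could drop the qualifying one).
#'
#' @param cohort an `ehr_cohort`
#' @param upgrades output of [evaluate_upgrades()]
#' @param limit code-count limit (> 0), default 25
#' @param payor_filter payor classes to include, default `"MEDICARE"`
#' @param payor_mapping mapping for [group_payor()]
#' @return named list: `at_limit`, `at_limit_upgrade_eligible`
#' @export
icd_limit_census <- function(cohort, upgrades, limit = 25,
                             payor_filter = "MEDICARE",
                             payor_mapping = default_payor_mapping()) {
  stopifnot(limit > 0)
  adm <- cohort$admissions
  n_codes <- lengths(split_icd_list(adm$billed_icd_codes))
  payor <- group_payor(adm$raw_financial_class, payor_mapping)
  sel <- payor %in% payor_filter & n_codes >= limit
  eligible_enc <- upgrades$encounter_id[upgrades$upgrade_type != "none"]
  list(at_limit = sum(sel),
       at_limit_upgrade_eligible = sum(sel & adm$encounter_id %in% eligible_enc))
}

#' Per-disease audit summary table
#'
#' One row per disease with four counts: admissions meeting the clinical
#' criteria (detected); detected admissions without any disease-specific
#' ICD code (missing, as a percent of detected); detected admissions whose
#' billed DRG modifier was inadequate for this disease (percent of
#' detected); and admissions carrying a disease-specific ICD code where the
#' algorithm was not sensitive (percent of the coded set, i.e. of
#' admissions bearing a qualifying code -- set
#' `not_sensitive_denominator = "detected"` for the detected-count
#' convention). A `Total` row sums the columns; admissions can contribute
#' to several rows, so the total exceeds the number of distinct admissions.
#'
#' @param findings output of [audit_findings()]
#' @param upgrades output of [evaluate_upgrades()]
#' @param not_sensitive_denominator `"coded"` (default) or `"detected"`
#' @return an `audit_table` data frame: `disease_name`, `detected`,
#'   `missing_icd`, `missing_icd_pct`, `drg_inadequate`,
#'   `drg_inadequate_pct`, `not_sensitive`, `not_sensitive_pct`
#' @export
build_audit_table <- function(findings, upgrades,
                              not_sensitive_denominator = c("coded", "detected")) {
  not_sensitive_denominator <- match.arg(not_sensitive_denominator)
  driving <- strsplit(upgrades$driving_diseases[upgrades$upgrade_type != "none"],
                      ";", fixed = TRUE)
  drv_enc <- rep(upgrades$encounter_id[upgrades$upgrade_type != "none"],
                 lengths(driving))
  drv_dis <- unlist(driving)
  drv_key <- paste(drv_enc, drv_dis, sep = "\r")
  f_key <- paste(findings$encounter_id, findings$disease_name, sep = "\r")
  findings$drg_inadequate <- f_key %in% drv_key

  pct <- function(num, den) ifelse(den > 0, round_half_up(100 * num / den, 1), 0)
  rows <- lapply(split(findings, findings$disease_name), function(f) {
    detected <- sum(f$detected)
    missing <- sum(f$missing_icd)
    drg <- sum(f$drg_inadequate)
    ns <- sum(f$icd_present & !f$detected)
    coded <- sum(f$icd_present)
    data.frame(disease_name = f$disease_name[1], detected = detected,
               missing_icd = missing, missing_icd_pct = pct(missing, detected),
               drg_inadequate = drg, drg_inadequate_pct = pct(drg, detected),
               not_sensitive = ns,
               not_sensitive_pct = pct(ns, if (not_sensitive_denominator == "coded")
                 coded else detected),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(disease_name = "Total", detected = sum(out$detected),
                    missing_icd = sum(out$missing_icd),
                    missing_icd_pct = pct(sum(out$missing_icd), sum(out$detected)),
                    drg_inadequate = sum(out$drg_inadequate),
                    drg_inadequate_pct = pct(sum(out$drg_inadequate), sum(out$detected)),
                    not_sensitive = sum(out$not_sensitive),
                    not_sensitive_pct = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(out, tot)
  rownames(out) <- NULL
  class(out) <- c("audit_table", "data.frame")
  out
}

#' @keywords internal
#' @noRd
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 35, 64, 78, Inf),
      labels = c("18-35 (young adult)", "36-64 (middle age)",
                 "65-78 (aged)", "79+ (old)"))
}

#' Demographic balance between accurate and unbilled coding
#'
#' Splits admissions into an accurate-coding group (no disease flagged as
#' missing its ICD code) and an unbilled group (at least one omission), then
#' reports per-variable standardized mean differences (binary for sex,
#' Mahalanobis-type for race/ethnicity, payor class and age band) and
#' per-category p-values against the reference categories
#' (Caucasian-Non-Hispanic, private payors, middle-aged 36-64; sex is a
#' single male-vs-female comparison).
#'
#' @param cohort an `ehr_cohort`
#' @param findings output of [audit_findings()]
#' @param test `"chisq"` (default) or `"fisher"` for the reference-group
#'   comparisons
#' @param payor_mapping mapping for [group_payor()]
#' @return data frame with columns `variable`, `category`, `accurate`,
#'   `unbilled`, `smd` (on the variable's first row), `p_value` (`NA` on
#'   reference rows)
#' @export
balance_table <- function(cohort, findings, test = "chisq",
                          payor_mapping = default_payor_mapping()) {
  adm <- cohort$admissions
  unbilled_enc <- unique(findings$encounter_id[findings$missing_icd])
  grp <- ifelse(adm$encounter_id %in% unbilled_enc, "unbilled", "accurate")
  vars <- list(
    Sex = list(values = factor(adm$sex, levels = c("male", "female")),
               ref = "female"),
    `Race / Ethnicity` = list(values = factor(adm$race_ethnicity,
                                              levels = RACE_LEVELS),
                              ref = "Caucasian-Non-Hispanic"),
    `Payor Group` = list(values = factor(group_payor(adm$raw_financial_class,
                                                     payor_mapping),
                                         levels = PAYOR_CLASSES),
                         ref = "PRIVATE"),
    `Age Group` = list(values = age_band(adm$age_years),
                       ref = "36-64 (middle age)"))
  out <- list()
  for (vn in names(vars)) {
    v <- vars[[vn]]
    tab <- table(v$values, factor(grp, levels = c("accurate", "unbilled")))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
    smd <- if (any(colSums(m) == 0)) NA_real_  # a group is empty: undefined
    else if (nrow(m) == 2) smd_binary(m[1, 1], sum(m[, 1]), m[1, 2], sum(m[, 2]))
    else smd_multicategory(m)
    ref <- v$ref
    for (i in seq_len(nrow(m))) {
      cat_name <- rownames(m)[i]
      pv <- if (cat_name == ref) NA_real_ else {
        sub <- rbind(m[i, ], m[ref, ])
        if (any(rowSums(sub) == 0) || any(colSums(sub) == 0)) NA_real_ else
          reference_group_test(sub, method = test)
      }
      out[[length(out) + 1]] <- data.frame(
        variable = vn, category = cat_name, accurate = m[i, 1],
        unbilled = m[i, 2], smd = if (i == 1) smd else NA_real_,
        p_value = pv, reference = cat_name == ref, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
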