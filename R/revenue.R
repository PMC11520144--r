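# Payor consolidation and relative-weighting-factor (RWF) valuation of
# flagged DRG upgrades. Dollar arithmetic is carried in exact cents with
# half-up rounding at the line level; per-type subtotals are additionally
# printed to the nearest dollar in summaries.

PAYOR_CLASSES <- c("MEDI-CAL", "MEDICARE", "PRIVATE")

#' Default raw-financial-class to payor-class mapping
#'
#' Medicaid and Medi-Cal consolidate to `MEDI-CAL`; Medicare and Medicare
#' Advantage consolidate to `MEDICARE`; everything else falls into the
#' `PRIVATE` bucket.
#'
#' @return named character vector, uppercase raw class to payor class
#' @export
default_payor_mapping <- function() {
  c("MEDI-CAL" = "MEDI-CAL", "MEDICAID" = "MEDI-CAL",
    "MEDICARE" = "MEDICARE", "MEDICARE ADVANTAGE" = "MEDICARE")
}

#' Default dollars-per-RWF rate schedule
#'
#' Estimated 2019 value of a single RWF point by payor class: $20,000 for
#' private payors, $10,000 for Medicare, and $7,500 for Medi-Cal. These are
#' estimates; any revenue they produce is an estimated figure.
#'
#' @return named numeric vector over the three payor classes
#' @export
default_rate_schedule <- function() {
  c("MEDI-CAL" = 7500, "MEDICARE" = 10000, "PRIVATE" = 20000)
}

#' @keywords internal
#' @noRd
check_rates <- function(rates) {
  if (!all(PAYOR_CLASSES %in% names(rates)) || any(rates[PAYOR_CLASSES] <= 0)) {
    stop("rate schedule must give a positive dollars-per-RWF value for MEDI-CAL, MEDICARE and PRIVATE",
         call. = FALSE)
  }
  rates
}

#' Consolidate a raw financial class into a payor class
#'
#' Exact (case-insensitive, trimmed) lookup against the mapping; anything
#' unmapped lands in the default `PRIVATE` bucket, so this never errors.
#'
#' @param raw_financial_class character vector of raw EHR financial classes
#' @param mapping named vector as from [default_payor_mapping()], or a path
#'   to a YAML file of `raw: class` pairs
#' @return character vector over `MEDI-CAL`, `MEDICARE`, `PRIVATE`
#' @examples
#' group_payor(c("Medicare Advantage", "Medicaid", "Blue Shield PPO"))
#' @export
group_payor <- function(raw_financial_class, mapping = default_payor_mapping()) {
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    mapping <- unlist(yaml::read_yaml(mapping))
  }
  names(mapping) <- toupper(trimws(names(mapping)))
  key <- toupper(trimws(raw_financial_class))
  out <- unname(mapping[key])
  out[is.na(out)] <- "PRIVATE"
  out
}

#' Value one flagged upgrade in dollars
#'
#' Delta RWF times the payor's dollars-per-RWF rate, rounded half-up to the
#' cent. A flag of type `"none"` values to $0.
#'
#' @param flag a one-row upgrade flag (needs `upgrade_type`, `delta_rwf`),
#'   or a bare numeric delta RWF
#' @param payor one of `MEDI-CAL`, `MEDICARE`, `PRIVATE`
#' @param rates rate schedule as from [default_rate_schedule()]
#' @return estimated lost revenue in dollars
#' @examples
#' value_upgrade(1.0, "PRIVATE")      # 20000
#' value_upgrade(0.3333, "MEDI-CAL")  # 2499.75
#' @export
value_upgrade <- function(flag, payor, rates = default_rate_schedule()) {
  rates <- check_rates(rates)
  delta <- if (is.numeric(flag)) flag else {
    if (identical(flag$upgrade_type, "none")) 0 else flag$delta_rwf
  }
  round_half_up(delta * unname(rates[payor]), 2)
}

#' Summarize flagged upgrades into a payor-stratified revenue table
#'
#' One line per non-empty (upgrade type, payor) cell with the admission
#' count, summed delta-RWF points, the dollars-per-RWF unit rate, and the
#' additional revenue (points x rate, half-up to the cent). Per-type
#' subtotals and the grand total (sum of the lines, to the cent) are
#' attached. Scaling every rate by a constant scales every dollar figure by
#' the same constant.
#'
#' @param flags data frame of upgrade flags with columns `upgrade_type`,
#'   `payor`, `delta_rwf` (rows with type `"none"` are dropped). A
#'   pre-aggregated table with `count` and `added_points` columns in place
#'   of `delta_rwf` is also accepted.
#' @param rates rate schedule as from [default_rate_schedule()]
#' @return a `revenue_summary`: list with `lines` (the per-cell table),
#'   `subtotals` (named by upgrade type, in dollars), and `grand_total`
#' @export
summarize_revenue <- function(flags, rates = default_rate_schedule()) {
  rates <- check_rates(rates)
  flags <- flags[flags$upgrade_type != "none", , drop = FALSE]
  if (!nrow(flags)) {
    lines <- data.frame(upgrade_type = character(0), payor = character(0),
                        count = integer(0), added_points = numeric(0),
                        dollars_per_unit = numeric(0),
                        additional_revenue = numeric(0),
                        stringsAsFactors = FALSE)
  } else if (all(c("count", "added_points") %in% names(flags))) {
    lines <- data.frame(upgrade_type = flags$upgrade_type, payor = flags$payor,
                        count = as.integer(flags$count),
                        added_points = flags$added_points,
                        stringsAsFactors = FALSE)
  } else {
    lines <- stats::aggregate(
      cbind(count = rep(1L, nrow(flags)), added_points = flags$delta_rwf),
      by = list(upgrade_type = flags$upgrade_type, payor = flags$payor), sum)
    lines$count <- as.integer(lines$count)
  }
  if (nrow(lines)) {
    lines <- lines[order(match(lines$upgrade_type, UPGRADE_TYPES),
                         match(lines$payor, PAYOR_CLASSES)), , drop = FALSE]
    lines$dollars_per_unit <- unname(rates[lines$payor])
    lines$additional_revenue <-
      round_half_up(lines$added_points * lines$dollars_per_unit, 2)
    rownames(lines) <- NULL
  }
  subtotals <- vapply(
    setdiff(UPGRADE_TYPES, "none"),
    function(tp) sum(lines$additional_revenue[lines$upgrade_type == tp]),
    numeric(1))
  structure(list(lines = lines, subtotals = subtotals,
                 grand_total = sum(lines$additional_revenue)),
            class = "revenue_summary")
}

#' @export
print.revenue_summary <- function(x, ...) {
  cat("Estimated additional revenue from proposed DRG upgrades\n")
  if (nrow(x$lines)) {
    df <- x$lines
    df$added_points <- formatC(df$added_points, format = "fg", digits = 10)
    df$additional_revenue <- sprintf("$%s",
                                     formatC(df$additional_revenue, format = "f",
                                             digits = 2, big.mark = ","))
    print(df, row.names = FALSE)
  } else {
    cat("  (no flagged upgrades)\n")
  }
  for (tp in names(x$subtotals)) {
    cat(sprintf("  subtotal %-12s $%s\n", tp,
                formatC(round_half_up(x$subtotals[[tp]], 0),
                        format = "f", digits = 0, big.mark = ",")))
  }
  cat(sprintf("  grand total (estimated): $%s\n",
              formatC(x$grand_total, format = "f", digits = 2,
                      big.mark = ",")))
  invisible(x)
}
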