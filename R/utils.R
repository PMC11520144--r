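# Internal helpers shared across modules.

SECONDS_PER_DAY <- 86400

#' @keywords internal
#' @noRd
as_days <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x) / SECONDS_PER_DAY)
  as.numeric(x)
}

# Half-up decimal rounding in exact integer cents. Base round() is
# round-half-even, which does not reproduce published revenue cells.
#' Round half-up at a fixed number of decimal digits
#'
#' Dollar arithmetic in this package rounds half-up at the line level, i.e.
#' `round_half_up(x, 2)` works in exact cents. A small epsilon guards the
#' products of decimal weights and integer rates against binary-float
#' representation error.
#'
#' @param x numeric vector
#' @param digits number of decimal digits to keep
#' @return numeric vector rounded half-up
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) gives 2
#' round_half_up(75.4941 * 7500, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize an ICD-10 code: uppercase, strip all whitespace.
#' @keywords internal
#' @noRd
normalize_icd <- function(codes) {
  toupper(gsub("\\s+", "", codes))
}

# Split / join the semicolon-packed ICD list column used in admissions
# tables. Empty string <-> character(0).
#' @keywords internal
#' @noRd
split_icd_list <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) unique(normalize_icd(v[nzchar(v)])))
}

#' @keywords internal
#' @noRd
join_icd_list <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

#' @keywords internal
#' @noRd
fmt_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  } else {
    # de-identified relative offsets in fractional days
    formatC(as.numeric(x), format = "fg", digits = 15)
  }
}

# Parse a timestamp column read from CSV: ISO-8601 strings or bare numeric
# day offsets (the de-identified form). Errors name the offending rows.
#' @keywords internal
#' @noRd
parse_time <- function(x, file, column) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(x)
  if (all(blank)) return(as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC"))
  num_like <- grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", x[!blank])
  if (all(num_like)) {
    out <- rep(NA_real_, length(x))
    out[!blank] <- as.numeric(x[!blank])
    return(out)
  }
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  out[blank] <- NA
  bad <- which(!blank & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable timestamp in %s column '%s' at row(s) %s",
                 file, column, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  out
}
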