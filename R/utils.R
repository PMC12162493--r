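# Shared helpers: FAERS date handling and number formatting.

# FAERS dates are YYYYMMDD strings; quarterly files also carry partial
# 4-digit (YYYY) and 6-digit (YYYYMM) values and empty strings.
# Classify each string; anything non-empty that is not a valid calendar
# YYYYMMDD counts as "partial".
faers_date_status <- function(x) {
  x <- ifelse(is.na(x), "", trimws(as.character(x)))
  status <- rep("partial", length(x))
  status[x == ""] <- "missing"
  full <- grepl("^[0-9]{8}$", x)
  d <- rep(as.Date(NA), length(x))
  d[full] <- as.Date(x[full], format = "%Y%m%d")
  status[full & !is.na(d)] <- "full"
  list(status = status, date = d)
}

#' Parse a FAERS YYYYMMDD date string
#'
#' Returns a `Date` for valid 8-digit values and `NA` for missing, partial
#' (4- or 6-digit) or malformed strings.
#'
#' @param x Character vector of FAERS-style date strings.
#' @return A `Date` vector with `NA` where no full calendar date is present.
#' @export
parse_faers_date <- function(x) {
  faers_date_status(x)$date
}

# Format a Date vector back to the FAERS YYYYMMDD dialect.
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(d)] <- ""
  out
}

# Two-decimal rendering with thousands separators, as signal tables print
# their statistics ("40,653.32").
fmt_stat <- function(x) {
  out <- formatC(x, digits = 2, format = "f", big.mark = ",")
  out[!is.finite(x)] <- NA_character_
  out
}

# "point (lower-upper)" cell, en dash separator.
fmt_interval <- function(point, lower, upper) {
  out <- paste0(fmt_stat(point), " (", fmt_stat(lower), "–", fmt_stat(upper), ")")
  out[!is.finite(point)] <- NA_character_
  out
}

# "point (aux)" cell, e.g. PRR with its chi-squared.
fmt_aux <- function(point, aux) {
  out <- paste0(fmt_stat(point), " (", fmt_stat(aux), ")")
  out[!is.finite(point)] <- NA_character_
  out
}

# Derive a stage-local 32-bit seed from a master seed, so every stage of a
# pipeline run draws from an independent, reproducible stream.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}
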