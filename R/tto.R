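# Time-to-onset: calendar days from therapy start (START_DT) to event onset
# (EVENT_DT). Reports with missing or unreasonable dates are excluded with a
# recorded reason; a 0-day interval is kept (same-day infusion reactions are
# clinically real).

#' Compute per-report time-to-onset records
#'
#' `tto_days = event_dt - start_dt` in calendar days when both are full
#' 8-digit dates, the interval is non-negative, and both dates fall within
#' `[1900-01-01, extraction_date]`. Otherwise the report is excluded with
#' the first applicable reason among `missing_event`, `missing_start`,
#' `partial_date` (which also covers malformed non-empty strings),
#' `negative_interval`, `out_of_range`.
#'
#' @param rs A `report_set` (typically filtered to the study drugs).
#' @param extraction_date Upper plausibility bound for both dates, `Date` or
#'   YYYYMMDD string (default the end of the study window, 2024-06-30).
#' @return A tibble with `primaryid`, `drug`, `sex`, `tto_days` (integer or
#'   NA), `exclusion_reason` (`"none"` for included records). Every report
#'   of `rs` appears exactly once.
#' @export
compute_tto <- function(rs, extraction_date = "20240630") {
  stopifnot(inherits(rs, "report_set"))
  if (!inherits(extraction_date, "Date")) {
    extraction_date <- as.Date(as.character(extraction_date),
                               format = "%Y%m%d")
  }
  lower_bound <- as.Date("1900-01-01")
  ev <- faers_date_status(rs$reports$event_dt)
  st <- faers_date_status(rs$reports$start_dt)
  diff_days <- as.integer(ev$date - st$date)
  in_range <- ev$date >= lower_bound & ev$date <= extraction_date &
    st$date >= lower_bound & st$date <= extraction_date

  reason <- dplyr::case_when(
    ev$status == "missing" ~ "missing_event",
    st$status == "missing" ~ "missing_start",
    ev$status == "partial" | st$status == "partial" ~ "partial_date",
    diff_days < 0 ~ "negative_interval",
    !in_range ~ "out_of_range",
    .default = "none"
  )
  tibble(
    primaryid = rs$reports$primaryid,
    drug = rs$reports$target_drug,
    sex = rs$reports$sex,
    tto_days = ifelse(reason == "none", diff_days, NA_integer_),
    exclusion_reason = reason
  )
}

#' Summarise time-to-onset by group
#'
#' @param records Tibble from [compute_tto()].
#' @param group_by `"drug"` or `"drug_sex"` (drug crossed with sex; records
#'   with missing sex form their own group only under `"drug"`).
#' @return One row per group: `n_included`, per-reason exclusion counts,
#'   `median_days`, `q1_days`, `q3_days`. The median of an even-sized sample
#'   is the midpoint of the two central order statistics, so half-day
#'   medians arise naturally. Empty groups keep `n_included = 0` with NA
#'   summaries.
#' @export
tto_summary <- function(records, group_by = c("drug", "drug_sex")) {
  group_by <- match.arg(group_by)
  grp <- if (group_by == "drug") "drug" else c("drug", "sex")
  if (group_by == "drug_sex") {
    records <- filter(records, !is.na(.data$sex))
  }
  records |>
    summarise(
      n_included = sum(.data$exclusion_reason == "none"),
      n_missing_event = sum(.data$exclusion_reason == "missing_event"),
      n_missing_start = sum(.data$exclusion_reason == "missing_start"),
      n_partial_date = sum(.data$exclusion_reason == "partial_date"),
      n_negative_interval = sum(.data$exclusion_reason == "negative_interval"),
      n_out_of_range = sum(.data$exclusion_reason == "out_of_range"),
      median_days = if (any(.data$exclusion_reason == "none"))
        median(.data$tto_days[.data$exclusion_reason == "none"]) else NA_real_,
      q1_days = if (any(.data$exclusion_reason == "none"))
        unname(quantile(.data$tto_days[.data$exclusion_reason == "none"],
                        0.25)) else NA_real_,
      q3_days = if (any(.data$exclusion_reason == "none"))
        unname(quantile(.data$tto_days[.data$exclusion_reason == "none"],
                        0.75)) else NA_real_,
      .by = dplyr::all_of(grp)
    ) |>
    arrange(dplyr::across(dplyr::all_of(grp)))
}

mw_u_from_ranks <- function(r_pool, idx1, n1) {
  sum(r_pool[idx1]) - n1 * (n1 + 1) / 2
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' When both groups have at most `exact_max_n` observations the two-sided
#' p-value is computed by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` assignments of the pooled mid-ranks:
#' `p = P(|U - E| >= |u_obs - E|)`, which handles ties exactly (fully tied
#' groups give p = 1). Larger samples use the normal approximation with the
#' tie-corrected variance and no continuity correction.
#'
#' @param group_a,group_b Numeric vectors of (e.g.) onset days; both
#'   non-empty.
#' @param exact_max_n Enumeration cutoff per group (default 8).
#' @return A one-row tibble: `statistic` (the Mann-Whitney U of `group_a`),
#'   `p_value`, `test_name`.
#' @export
#' @examples
#' compare_tto(c(1, 2, 3), c(10, 20, 30))  # exact p = 0.100
compare_tto <- function(group_a, group_b, exact_max_n = 8) {
  group_a <- as.numeric(group_a[!is.na(group_a)])
  group_b <- as.numeric(group_b[!is.na(group_b)])
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty.")
  pool <- c(group_a, group_b)
  r <- rank(pool)  # mid-ranks under ties
  u_obs <- mw_u_from_ranks(r, seq_len(n1), n1)
  e_u <- n1 * n2 / 2

  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    assignments <- combn(n1 + n2, n1)
    u_all <- apply(assignments, 2L, function(idx) mw_u_from_ranks(r, idx, n1))
    tol <- sqrt(.Machine$double.eps)
    p <- mean(abs(u_all - e_u) >= abs(u_obs - e_u) - tol)
    test_name <- "Mann-Whitney (exact enumeration)"
  } else {
    n <- n1 + n2
    ties <- table(pool)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_u <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v_u <= 0) {
      p <- 1
    } else {
      z <- (u_obs - e_u) / sqrt(v_u)
      p <- 2 * pnorm(-abs(z))
    }
    test_name <- "Mann-Whitney (normal approximation, tie-corrected)"
  }
  tibble(statistic = u_obs, p_value = min(1, p), test_name = test_name)
}
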