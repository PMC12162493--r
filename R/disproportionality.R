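# The four signal-detection algorithms on a 2x2 table (cells a, b, c, d,
# N = a + b + c + d), their interval estimates, each algorithm's positivity
# criteria, and the conservative consensus rule (a signal is positive only
# when all four algorithms flag it):
#
#   ROR  = ad / bc, Wald 95% CI on the log scale; positive iff CI lower > 1
#          and a >= 3.
#   PRR  = [a/(a+b)] / [c/(c+d)] with the Pearson chi-squared statistic (no
#          continuity correction); positive iff PRR >= 2, chi2 >= 4, a >= 3.
#   BCPNN information component (posterior closed form):
#          gamma = (N+2)^2 / ((a+b+1)(a+c+1))
#          EIC   = log2[ (a+1)(N+2)^2 / ((N+gamma)(a+b+1)(a+c+1)) ]
#          VIC   = (1/ln 2)^2 [ (b+c+d+gamma-1)/((a+1)(N+gamma+1))
#                             + (c+d+1)/((a+b+1)(N+3))
#                             + (b+d+1)/((a+c+1)(N+3)) ]
#          IC025 = EIC - 2 sqrt(VIC); positive iff IC025 > 0.
#   MGPS closed-form empirical Bayes geometric mean:
#          EBGM = aN / ((a+c)(a+b)), EBGM05 = exp(ln EBGM - z sqrt(1/a + 1/b
#          + 1/c + 1/d)); positive iff EBGM05 >= 2 and a > 0.
#
# No continuity / Yates correction anywhere; zero cells leave ROR, the PRR
# CI and EBGM05 undefined rather than corrected (the a >= 3 gate makes a = 0
# moot for positivity). Statistics are computed at full precision and
# rounded only at rendering.

#' Compute all four disproportionality statistics (vectorised)
#'
#' @param a,b,c,d Non-negative integer cell counts (recycled to a common
#'   length): target drug + term, other drugs + term, target drug + other
#'   terms, other drugs + other terms.
#' @param z Normal quantile for the ROR / PRR / EBGM interval estimates
#'   (default 1.96, the two-sided 95% level).
#' @param z_ebgm Quantile for EBGM05. The conventional one-sided 95% bound
#'   would use 1.645; 1.96 is the default here, matching the two-sided
#'   convention most FAERS analyses print.
#' @param min_a Minimum case count shared by the ROR and PRR criteria.
#' @param ror_lower_min,prr_min,chisq_min,ic025_min,ebgm05_min Positivity
#'   thresholds (defaults are the standard criteria).
#' @return A tibble, one row per table, with the point estimates, interval
#'   bounds, auxiliary quantities (`chisq`, `gamma`, `vic`), per-algorithm
#'   `*_defined` and `*_positive` flags and `consensus_positive` (the AND of
#'   the four).
#' @export
#' @examples
#' disproportionality_stats(20, 10, 10, 20)
disproportionality_stats <- function(a, b, c, d,
                                     z = 1.96, z_ebgm = 1.96,
                                     min_a = 3,
                                     ror_lower_min = 1,
                                     prr_min = 2, chisq_min = 4,
                                     ic025_min = 0, ebgm05_min = 2) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, n)); b <- as.numeric(rep_len(b, n))
  c <- as.numeric(rep_len(c, n)); d <- as.numeric(rep_len(d, n))
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative.")
  N <- a + b + c + d

  all_pos <- a > 0 & b > 0 & c > 0 & d > 0
  se_or <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)

  # ROR
  ror <- ifelse(all_pos, (a * d) / (b * c), NA_real_)
  ror_lower <- exp(log(ror) - z * se_or)
  ror_upper <- exp(log(ror) + z * se_or)
  ror_positive <- all_pos & !is.na(ror_lower) & ror_lower > ror_lower_min &
    a >= min_a

  # PRR and Pearson chi-squared
  prr_defined <- (a + b) > 0 & c > 0 & (c + d) > 0
  prr <- ifelse(prr_defined, (a / (a + b)) / (c / (c + d)), NA_real_)
  chisq_defined <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chisq <- ifelse(chisq_defined,
                  (a * d - b * c)^2 * N /
                    ((a + b) * (c + d) * (a + c) * (b + d)),
                  NA_real_)
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  prr_lower <- ifelse(prr_defined & a > 0, exp(log(prr) - z * se_prr),
                      NA_real_)
  prr_upper <- ifelse(prr_defined & a > 0, exp(log(prr) + z * se_prr),
                      NA_real_)
  prr_positive <- prr_defined & chisq_defined & prr >= prr_min &
    chisq >= chisq_min & a >= min_a

  # BCPNN information component (defined for all non-negative cells)
  gamma <- (N + 2)^2 / ((a + b + 1) * (a + c + 1))
  eic <- log2((a + 1) * (N + 2)^2 / ((N + gamma) * (a + b + 1) * (a + c + 1)))
  vic <- (1 / log(2))^2 * (
    (b + c + d + gamma - 1) / ((a + 1) * (N + gamma + 1)) +
    (c + d + 1) / ((a + b + 1) * (N + 3)) +
    (b + d + 1) / ((a + c + 1) * (N + 3))
  )
  ic025 <- eic - 2 * sqrt(vic)
  bcpnn_positive <- ic025 > ic025_min

  # MGPS closed-form EBGM
  ebgm_defined <- (a + c) > 0 & (a + b) > 0
  ebgm <- ifelse(ebgm_defined, a * N / ((a + c) * (a + b)), NA_real_)
  ebgm05 <- ifelse(all_pos, exp(log(ebgm) - z_ebgm * se_or), NA_real_)
  ebgm_upper <- ifelse(all_pos, exp(log(ebgm) + z_ebgm * se_or), NA_real_)
  mgps_positive <- all_pos & !is.na(ebgm05) & ebgm05 >= ebgm05_min & a > 0

  tibble(
    a = a, b = b, c = c, d = d, N = N,
    ror = ror, ror_lower = ror_lower, ror_upper = ror_upper,
    ror_defined = all_pos, ror_positive = ror_positive,
    prr = prr, chisq = chisq, prr_lower = prr_lower, prr_upper = prr_upper,
    prr_defined = prr_defined, prr_positive = prr_positive,
    gamma = gamma, eic = eic, vic = vic, ic025 = ic025,
    bcpnn_defined = TRUE, bcpnn_positive = bcpnn_positive,
    ebgm = ebgm, ebgm05 = ebgm05, ebgm_upper = ebgm_upper,
    ebgm_defined = ebgm_defined, mgps_positive = mgps_positive,
    consensus_positive = ror_positive & prr_positive & bcpnn_positive &
      mgps_positive
  )
}

cells_from <- function(t, a, b, c, d) {
  if (!is.null(t)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
    list(a = t$a, b = t$b, c = t$c, d = t$d)
  } else {
    list(a = a, b = b, c = c, d = d)
  }
}

#' Single-algorithm results
#'
#' Each returns one row per table with the algorithm's point estimate,
#' interval, auxiliary quantities, and whether the estimate is defined and
#' meets its positivity criteria. `bcpnn_ic()`'s interval is the one-sided
#' IC025 lower bound.
#'
#' @param t A `contingency_table` (or any data frame with columns
#'   `a`,`b`,`c`,`d`); alternatively pass the cells directly.
#' @param a,b,c,d Cell counts, used when `t` is NULL.
#' @param ... Passed to [disproportionality_stats()] (thresholds, `z`,
#'   `z_ebgm`).
#' @return A tibble with columns `algorithm`, `point`, `lower`, `upper`,
#'   algorithm-specific auxiliaries, `defined`, `positive`.
#' @export
#' @examples
#' ror(a = 20, b = 10, c = 10, d = 20)
ror <- function(t = NULL, a = NULL, b = NULL, c = NULL, d = NULL, ...) {
  x <- cells_from(t, a, b, c, d)
  s <- disproportionality_stats(x$a, x$b, x$c, x$d, ...)
  tibble(algorithm = "ROR", point = s$ror, lower = s$ror_lower,
         upper = s$ror_upper, defined = s$ror_defined,
         positive = s$ror_positive)
}

#' @rdname ror
#' @export
prr <- function(t = NULL, a = NULL, b = NULL, c = NULL, d = NULL, ...) {
  x <- cells_from(t, a, b, c, d)
  s <- disproportionality_stats(x$a, x$b, x$c, x$d, ...)
  tibble(algorithm = "PRR", point = s$prr, lower = s$prr_lower,
         upper = s$prr_upper, chisq = s$chisq, defined = s$prr_defined,
         positive = s$prr_positive)
}

#' @rdname ror
#' @export
bcpnn_ic <- function(t = NULL, a = NULL, b = NULL, c = NULL, d = NULL, ...) {
  x <- cells_from(t, a, b, c, d)
  s <- disproportionality_stats(x$a, x$b, x$c, x$d, ...)
  tibble(algorithm = "BCPNN", point = s$eic, lower = s$ic025,
         upper = NA_real_, vic = s$vic, gamma = s$gamma,
         defined = s$bcpnn_defined, positive = s$bcpnn_positive)
}

#' @rdname ror
#' @export
ebgm <- function(t = NULL, a = NULL, b = NULL, c = NULL, d = NULL, ...) {
  x <- cells_from(t, a, b, c, d)
  s <- disproportionality_stats(x$a, x$b, x$c, x$d, ...)
  tibble(algorithm = "MGPS", point = s$ebgm, lower = s$ebgm05,
         upper = s$ebgm_upper, ebgm05 = s$ebgm05, defined = s$ebgm_defined,
         positive = s$mgps_positive)
}

#' Run all four algorithms on one table and apply the consensus rule
#'
#' A drug-event pair is a consensus-positive signal only when it
#' simultaneously satisfies the threshold criteria of all four algorithms.
#'
#' @param t A one-row `contingency_table` (or data frame with `a,b,c,d`).
#' @param ... Threshold / quantile overrides, passed through.
#' @return A `signal_result`: list with `table`, `results` (four-row tibble),
#'   and `consensus_positive`.
#' @export
evaluate_consensus <- function(t, ...) {
  stopifnot(nrow(t) == 1)
  results <- bind_rows(
    ror(t, ...), prr(t, ...), bcpnn_ic(t, ...), ebgm(t, ...)
  )
  structure(
    list(table = t, results = results,
         consensus_positive = all(results$positive)),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat("<signal_result>",
      if (x$consensus_positive) "consensus POSITIVE" else "not positive",
      "\n")
  print(x$results)
  invisible(x)
}

#' Screen a set of contingency tables
#'
#' One row per table with the frequency (`a`), all four statistics with
#' their intervals and auxiliaries at full precision, per-algorithm flags,
#' the consensus flag, and display columns formatted to two decimals in the
#' conventional layouts `ROR (95% CI)` as `"6.08 (5.56–6.64)"`, `PRR (chi2)`,
#' `EBGM (EBGM05)` and `IC (IC025)`.
#'
#' @param tables A `contingency_table` tibble from [enumerate_tables()].
#' @param ... Threshold / quantile overrides for
#'   [disproportionality_stats()].
#' @return A tibble sorted as the input (descending `a`), sortable by any
#'   statistic column.
#' @export
screen_signals <- function(tables, ...) {
  meta_cols <- intersect(c("drug", "level", "stratum", "term"), names(tables))
  if (nrow(tables) == 0) {
    return(tibble(drug = character(), level = character(),
                  stratum = character(), term = character(),
                  frequency = integer()))
  }
  s <- disproportionality_stats(tables$a, tables$b, tables$c, tables$d, ...)
  bind_cols(tables[meta_cols], rename(s, frequency = "a")) |>
    mutate(
      ror_ci = fmt_interval(.data$ror, .data$ror_lower, .data$ror_upper),
      prr_chisq = fmt_aux(.data$prr, .data$chisq),
      ebgm_ebgm05 = fmt_aux(.data$ebgm, .data$ebgm05),
      ic_ic025 = fmt_aux(.data$eic, .data$ic025)
    )
}
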