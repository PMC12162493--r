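#' Default drug universe for the synthetic reporting database
#'
#' Two anti-amyloid target drugs with their brand names plus a pool of
#' background comparator drugs. Brand (product) names matter because
#' primary-suspect filtering matches free-text `drugname`/`prodname` fields.
#'
#' @param n_background Number of background comparator drugs.
#' @return A tibble with columns `drugname`, `prodname`, `target` (logical).
#' @export
default_drug_table <- function(n_background = 8) {
  stopifnot(n_background >= 1)
  bg <- sprintf("backgrounddrug%02d", seq_len(n_background))
  tibble(
    drugname = c("lecanemab", "aducanumab", bg),
    prodname = c("leqembi", "aduhelm", bg),
    target   = c(TRUE, TRUE, rep(FALSE, n_background))
  )
}

#' Default preferred-term catalog
#'
#' A synthetic stand-in for a MedDRA PT to primary-SOC map (the real
#' dictionary is licensed and cannot be bundled). PTs are spread evenly over
#' the SOCs.
#'
#' @param n_pt Number of preferred terms.
#' @param n_soc Number of system organ classes.
#' @return A tibble with columns `pt`, `soc`.
#' @export
default_pt_catalog <- function(n_pt = 60, n_soc = 10) {
  stopifnot(n_pt >= 1, n_soc >= 1, n_soc <= n_pt)
  tibble(
    pt  = sprintf("PT_%03d", seq_len(n_pt)),
    soc = sprintf("SOC_%02d", ((seq_len(n_pt) - 1L) %% n_soc) + 1L
    )
  )
}

#' Configuration for the synthetic spontaneous-reporting generator
#'
#' Bundles and validates every knob of the generator: the drug universe, the
#' PT catalog, planted drug-event associations with their relative risks,
#' demographic missingness rates, the report date window, and per-drug
#' time-to-onset distributions.
#'
#' Defaults emulate the structure of a FAERS extract for the two anti-amyloid
#' antibodies: a female-leaning sex mix with ~6.7% missing sex, ~26% missing
#' age, mostly-US reporting, log-normal time-to-onset with medians 33 days
#' (lecanemab) and 146 days (aducanumab), and a background of drug-event
#' independence on which associated pairs are planted at known relative risk.
#'
#' @param n_cases Number of unique cases to simulate.
#' @param drugs Drug table as returned by [default_drug_table()].
#' @param pt_catalog PT/SOC catalog as returned by [default_pt_catalog()].
#' @param planted_signals Tibble with columns `drug`, `pt`, `rr` (relative
#'   risk, all >= 1). PT occurrence probability for reports whose primary
#'   suspect is `drug` is multiplied by `rr` (clipped to 1).
#' @param background_pt_rate Mean number of PTs per report under independence;
#'   each PT occurs with probability `background_pt_rate / nrow(pt_catalog)`.
#' @param duplicate_rate Fraction of cases emitted under more than one
#'   primaryid version.
#' @param missing_sex_rate,missing_age_rate,missing_date_rate Fractions of
#'   reports with the field blanked.
#' @param partial_date_rate Fraction of dates truncated to 4- or 6-digit
#'   partial values (FAERS carries such records).
#' @param tto_distributions Named list of per-drug time-to-onset
#'   distributions; each element is `list(family, ...)` with family
#'   `"lognormal"` (`meanlog`, `sdlog`) or `"gamma"` (`shape`, `rate`).
#'   A `.default` entry covers drugs without their own spec.
#' @param date_window Character vector of two YYYYMMDD dates bounding event
#'   dates.
#' @param seed Integer seed; identical config + seed reproduces the dataset
#'   byte for byte.
#' @return A validated `synthetic_config` object (a list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_cases = 500, seed = 42)
#' names(cfg)
synthetic_config <- function(n_cases = 10000,
                             drugs = default_drug_table(),
                             pt_catalog = default_pt_catalog(),
                             planted_signals = tibble(
                               drug = c("lecanemab", "lecanemab",
                                        "aducanumab", "aducanumab"),
                               pt   = c("PT_001", "PT_002", "PT_001", "PT_003"),
                               rr   = c(10, 5, 10, 5)
                             ),
                             background_pt_rate = 3,
                             duplicate_rate = 0.08,
                             missing_sex_rate = 0.067,
                             missing_age_rate = 0.26,
                             missing_date_rate = 0.15,
                             partial_date_rate = 0.05,
                             tto_distributions = list(
                               lecanemab  = list(family = "lognormal",
                                                 meanlog = log(33), sdlog = 1),
                               aducanumab = list(family = "lognormal",
                                                 meanlog = log(146), sdlog = 1),
                               .default   = list(family = "lognormal",
                                                 meanlog = log(60), sdlog = 1)
                             ),
                             date_window = c("20040101", "20240630"),
                             seed = 1L) {
  drugs <- as_tibble(drugs)
  pt_catalog <- as_tibble(pt_catalog)
  planted_signals <- as_tibble(planted_signals)

  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1) {
    abort("`n_cases` must be a positive integer.")
  }
  if (nrow(drugs) == 0) abort("configuration error: zero drugs.")
  if (!all(c("drugname", "prodname", "target") %in% names(drugs))) {
    abort("`drugs` needs columns drugname, prodname, target.")
  }
  if (!any(drugs$target)) abort("at least one target drug is required.")
  if (anyDuplicated(drugs$drugname)) abort("duplicate drug names.")
  if (nrow(pt_catalog) == 0) abort("configuration error: zero PTs.")
  if (!all(c("pt", "soc") %in% names(pt_catalog))) {
    abort("`pt_catalog` needs columns pt, soc.")
  }
  conflicts <- pt_catalog |>
    distinct(.data$pt, .data$soc) |>
    count(.data$pt) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("PT mapped to conflicting SOCs: ",
                 paste(conflicts$pt, collapse = ", ")))
  }
  pt_catalog <- distinct(pt_catalog)

  if (nrow(planted_signals) > 0) {
    if (!all(c("drug", "pt", "rr") %in% names(planted_signals))) {
      abort("`planted_signals` needs columns drug, pt, rr.")
    }
    bad_drug <- setdiff(planted_signals$drug, drugs$drugname)
    bad_pt <- setdiff(planted_signals$pt, pt_catalog$pt)
    if (length(bad_drug) || length(bad_pt)) {
      abort(paste0("configuration error: planted pair not in catalog (",
                   paste(c(bad_drug, bad_pt), collapse = ", "), ")."))
    }
    if (any(planted_signals$rr < 1)) {
      abort("planted relative risks must be >= 1.")
    }
  }

  rates <- c(duplicate_rate = duplicate_rate,
             missing_sex_rate = missing_sex_rate,
             missing_age_rate = missing_age_rate,
             missing_date_rate = missing_date_rate,
             partial_date_rate = partial_date_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1].")
  }
  if (background_pt_rate <= 0) abort("`background_pt_rate` must be positive.")
  if (length(date_window) != 2 || any(!grepl("^[0-9]{8}$", date_window)) ||
      date_window[1] > date_window[2]) {
    abort("`date_window` must be two YYYYMMDD strings, start <= end.")
  }
  if (is.null(tto_distributions$.default)) {
    abort("`tto_distributions` needs a `.default` entry.")
  }

  structure(
    list(
      n_cases = as.integer(n_cases),
      drugs = drugs,
      pt_catalog = pt_catalog,
      planted_signals = planted_signals,
      background_pt_rate = background_pt_rate,
      duplicate_rate = duplicate_rate,
      missing_sex_rate = missing_sex_rate,
      missing_age_rate = missing_age_rate,
      missing_date_rate = missing_date_rate,
      partial_date_rate = partial_date_rate,
      tto_distributions = tto_distributions,
      date_window = date_window,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  cases:", x$n_cases,
      "| drugs:", nrow(x$drugs),
      "(targets:", sum(x$drugs$target), ")",
      "| PTs:", nrow(x$pt_catalog),
      "| planted:", nrow(x$planted_signals), "\n")
  cat("  background PT rate:", x$background_pt_rate,
      "| duplicate rate:", x$duplicate_rate,
      "| seed:", x$seed, "\n")
  invisible(x)
}
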