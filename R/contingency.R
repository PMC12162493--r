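# 2x2 disproportionality tables. Cells, per the classical layout:
#   a  reports with the suspect drug and the suspect event
#   b  reports with all other drugs and the suspect event
#   c  reports with the suspect drug and other events
#   d  reports with other drugs and other events
# The counting unit is the report: a report with several PTs contributes to
# every term it mentions, but to each cell at most once.

stratum_ids <- function(rs, stratum) {
  r <- rs$reports
  switch(stratum,
    overall = r$primaryid,
    F = r$primaryid[!is.na(r$sex) & r$sex == "F"],
    M = r$primaryid[!is.na(r$sex) & r$sex == "M"],
    abort(paste0("unknown stratum label: ", stratum))
  )
}

term_rows <- function(rs, level) {
  switch(level,
    PT = rs$pt_rows,
    SOC = {
      if (!rs$mapped) abort("SOC-level counting requires map_meddra() first.")
      rename(rs$soc_rows, pt = "soc")
    },
    abort(paste0("level must be PT or SOC, got: ", level))
  )
}

check_disjoint <- function(target, background) {
  overlap <- intersect(target$reports$primaryid, background$reports$primaryid)
  if (length(overlap)) {
    abort(paste0(length(overlap),
                 " primaryids present in both target and background sets."))
  }
}

#' Build one 2x2 contingency table
#'
#' Counts reports of the target drug with / without the term against the
#' background comparator universe (all other drugs), optionally restricted to
#' one sex stratum on both sides.
#'
#' @param target `report_set` of target-drug reports (with `target_drug` set).
#' @param background `report_set` of comparator reports, disjoint from
#'   `target` by primaryid.
#' @param drug Canonical drug name to count on the target side.
#' @param term PT or SOC string.
#' @param level `"PT"` or `"SOC"`.
#' @param stratum `"overall"`, `"F"` or `"M"`.
#' @return A one-row `contingency_table` tibble with columns `drug`, `level`,
#'   `stratum`, `term`, `a`, `b`, `c`, `d`, `N`.
#' @export
#' @examples
#' # see enumerate_tables() for bulk screening
build_contingency <- function(target, background, drug, term,
                              level = c("PT", "SOC"),
                              stratum = "overall") {
  level <- match.arg(level)
  if (!nzchar(term)) abort("`term` must be non-empty.")
  out <- enumerate_tables(target, background, drug, level = level,
                          stratum = stratum, min_a = 0, terms = term)
  out
}

#' Enumerate contingency tables for every observed term
#'
#' One table per distinct term mentioned by at least `min_a` target-drug
#' reports in the stratum, sorted by descending `a` then term name.
#'
#' @inheritParams build_contingency
#' @param min_a Minimum `a` for a term to be kept (the shared screening
#'   criterion defaults to 3; SOC screening conventionally uses 1 so that
#'   sub-threshold rows are still printed).
#' @param terms Optional character vector restricting the terms counted
#'   (terms not mentioned by any report yield `a = 0` rows).
#' @return A `contingency_table` tibble, one row per term.
#' @export
enumerate_tables <- function(target, background, drug,
                             level = c("PT", "SOC"),
                             stratum = "overall", min_a = 3,
                             terms = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(target, "report_set"), inherits(background, "report_set"))
  check_disjoint(target, background)

  tgt_r <- target$reports
  if (!all(is.na(tgt_r$target_drug))) {
    tgt_r <- filter(tgt_r, .data$target_drug == drug)
  }
  tgt_ids <- intersect(tgt_r$primaryid, stratum_ids(target, stratum))
  bg_ids <- stratum_ids(background, stratum)
  n_tgt <- length(tgt_ids)
  n_bg <- length(bg_ids)

  # a report contributes to each term cell at most once
  tgt_terms <- term_rows(target, level) |>
    filter(.data$primaryid %in% tgt_ids) |>
    distinct(.data$primaryid, .data$pt) |>
    count(term = .data$pt, name = "a")
  bg_terms <- term_rows(background, level) |>
    filter(.data$primaryid %in% bg_ids) |>
    distinct(.data$primaryid, .data$pt) |>
    count(term = .data$pt, name = "b")

  if (is.null(terms)) {
    out <- filter(tgt_terms, .data$a >= min_a)
  } else {
    out <- tibble(term = terms) |>
      left_join(tgt_terms, by = "term") |>
      mutate(a = dplyr::coalesce(.data$a, 0L)) |>
      filter(.data$a >= min_a)
  }
  out <- out |>
    left_join(bg_terms, by = "term") |>
    mutate(
      b = dplyr::coalesce(.data$b, 0L),
      c = n_tgt - .data$a,
      d = n_bg - .data$b,
      N = .data$a + .data$b + .data$c + .data$d,
      drug = drug, level = level, stratum = stratum
    ) |>
    select("drug", "level", "stratum", "term", "a", "b", "c", "d", "N") |>
    arrange(dplyr::desc(.data$a), .data$term)
  class(out) <- c("contingency_table", class(out))
  out
}
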