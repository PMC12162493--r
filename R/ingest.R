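# Ingestion of FAERS-dialect quarterly tables into a relational report set:
# one row per primaryid in `reports`, with the DRUG, REAC and (derived) SOC
# rows kept long and keyed by primaryid, mirroring the source tables.

#' Construct a report set
#'
#' The container all pipeline stages operate on. `reports` holds one row per
#' report (primaryid); drug entries, PTs and SOCs are long tables keyed by
#' primaryid.
#'
#' @param reports Tibble with at least `primaryid` and `caseid`; optional
#'   columns `sex` ("F"/"M"/NA), `age_years`, `reporter_type`, `country`,
#'   `event_dt`, `start_dt` (raw YYYYMMDD strings), `target_drug`.
#' @param drug_rows Tibble `primaryid, drug_seq, role_cod, drugname, prodname`.
#' @param pt_rows Tibble `primaryid, pt` (one row per distinct report-PT pair).
#' @param soc_rows Tibble `primaryid, soc`, normally derived by [map_meddra()].
#' @param dedup_applied Has case-version deduplication been applied?
#' @param provenance Character vector of source file paths.
#' @return A `report_set` object.
#' @export
report_set <- function(reports,
                       drug_rows = NULL,
                       pt_rows = NULL,
                       soc_rows = NULL,
                       dedup_applied = FALSE,
                       provenance = character()) {
  reports <- as_tibble(reports)
  if (!all(c("primaryid", "caseid") %in% names(reports))) {
    abort("`reports` needs primaryid and caseid columns.")
  }
  for (col in c("sex", "reporter_type", "country", "event_dt", "start_dt",
                "target_drug")) {
    if (!col %in% names(reports)) reports[[col]] <- NA_character_
  }
  if (!"age_years" %in% names(reports)) reports$age_years <- NA_real_
  if (anyDuplicated(reports$primaryid)) {
    abort("duplicate primaryid in `reports`.")
  }
  empty <- function(...) tibble(...)
  structure(
    list(
      reports = reports,
      drug_rows = as_tibble(drug_rows %||%
        empty(primaryid = character(), drug_seq = integer(),
              role_cod = character(), drugname = character(),
              prodname = character())),
      pt_rows = as_tibble(pt_rows %||%
        empty(primaryid = character(), pt = character())),
      soc_rows = as_tibble(soc_rows %||%
        empty(primaryid = character(), soc = character())),
      dedup_applied = isTRUE(dedup_applied),
      mapped = !is.null(soc_rows),
      provenance = provenance,
      log = list()
    ),
    class = "report_set"
  )
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set>", nrow(x$reports), "reports |",
      nrow(x$pt_rows), "report-PT rows |",
      if (x$dedup_applied) "deduplicated" else "not deduplicated", "\n")
  if (length(x$log)) {
    cat("  log:", paste(names(x$log), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of reports in a report set
#' @param rs A `report_set`.
#' @return Integer count.
#' @export
n_reports <- function(rs) nrow(rs$reports)

#' @export
as_tibble.report_set <- function(x, ...) {
  pts <- x$pt_rows |>
    summarise(pts = list(unique(.data$pt)), .by = "primaryid")
  socs <- x$soc_rows |>
    summarise(socs = list(unique(.data$soc)), .by = "primaryid")
  x$reports |>
    left_join(pts, by = "primaryid") |>
    left_join(socs, by = "primaryid")
}

read_faers_file <- function(path) {
  readr::read_delim(path, delim = "$",
                    col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE)
}

normalise_age <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(ifelse(is.na(age_cod), "", age_cod))
  yrs <- dplyr::case_when(
    is.na(a) ~ NA_real_,
    cod %in% c("", "YR") ~ a,
    cod == "DEC" ~ a * 10,
    cod == "MON" ~ a / 12,
    cod == "WK" ~ a * 7 / 365.25,
    cod == "DY" ~ a / 365.25,
    cod == "HR" ~ a / (24 * 365.25),
    .default = NA_real_
  )
  ifelse(!is.na(yrs) & yrs < 0, NA_real_, yrs)
}

reporter_from_occp <- function(occp_cod) {
  cod <- toupper(ifelse(is.na(occp_cod), "", occp_cod))
  dplyr::case_when(
    cod == "CN" ~ "consumer",
    cod == "MD" ~ "physician",
    cod %in% c("HP", "OT") ~ "health-professional",
    cod == "PH" ~ "pharmacist",
    .default = NA_character_
  )
}

#' Parse FAERS quarterly tables into a report set
#'
#' Reads the '$'-delimited DEMO, DRUG, REAC and (optionally) THER tables,
#' builds one report per primaryid, collects REAC PTs as a set, and joins the
#' therapy start date of the primary-suspect drug via `dsg_drug_seq` (the
#' earliest full date when several THER rows exist). DRUG/REAC rows whose
#' primaryid is absent from DEMO are dropped and counted as orphans; reports
#' without any reaction row are dropped and counted. Nothing here is fatal
#' except a missing mandatory table.
#'
#' @param paths Either a named list/vector of file paths (`demo`, `drug`,
#'   `reac`, optional `ther`), a `synthetic_faers` object, or a named list of
#'   in-memory tables in the same layout.
#' @return A `report_set` (not yet deduplicated).
#' @export
parse_faers_tables <- function(paths) {
  provenance <- character()
  if (inherits(paths, "synthetic_faers")) {
    tables <- paths$tables
  } else if (is.list(paths) && all(vapply(paths, is.data.frame, logical(1)))) {
    tables <- paths
  } else {
    paths <- as.list(paths)
    names(paths) <- tolower(names(paths))
    missing_tbl <- setdiff(c("demo", "drug", "reac"), names(paths))
    if (length(missing_tbl)) {
      abort(paste0("mandatory table(s) missing: ",
                   paste(missing_tbl, collapse = ", ")))
    }
    tables <- lapply(paths, read_faers_file)
    provenance <- unlist(paths, use.names = FALSE)
  }
  names(tables) <- tolower(names(tables))
  missing_tbl <- setdiff(c("demo", "drug", "reac"), names(tables))
  if (length(missing_tbl)) {
    abort(paste0("mandatory table(s) missing: ",
                 paste(missing_tbl, collapse = ", ")))
  }

  demo <- as_tibble(tables$demo)
  names(demo) <- tolower(names(demo))
  if (!"sex" %in% names(demo) && "gndr_cod" %in% names(demo)) {
    demo$sex <- demo$gndr_cod
  }
  for (col in c("event_dt", "sex", "age", "age_cod", "occp_cod",
                "occr_country")) {
    if (!col %in% names(demo)) demo[[col]] <- NA_character_
  }
  n_raw <- nrow(demo)
  demo <- distinct(demo)
  exact_demo_dups <- n_raw - nrow(demo)
  conflicting <- sum(duplicated(demo$primaryid))
  demo <- demo |> filter(!duplicated(.data$primaryid))

  reports <- tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    sex = ifelse(demo$sex %in% c("F", "M"), demo$sex, NA_character_),
    age_years = normalise_age(demo$age, demo$age_cod),
    reporter_type = reporter_from_occp(demo$occp_cod),
    country = ifelse(is.na(demo$occr_country) | demo$occr_country == "",
                     NA_character_, demo$occr_country),
    event_dt = ifelse(is.na(demo$event_dt), "", demo$event_dt),
    start_dt = NA_character_,
    target_drug = NA_character_
  )

  drug <- as_tibble(tables$drug)
  names(drug) <- tolower(names(drug))
  if (!"prodname" %in% names(drug)) drug$prodname <- NA_character_
  drug_orphans <- sum(!drug$primaryid %in% reports$primaryid)
  drug <- drug |>
    filter(.data$primaryid %in% reports$primaryid) |>
    mutate(drug_seq = suppressWarnings(as.integer(.data$drug_seq))) |>
    select("primaryid", "drug_seq", "role_cod", "drugname", "prodname")

  reac <- as_tibble(tables$reac)
  names(reac) <- tolower(names(reac))
  reac_orphans <- sum(!reac$primaryid %in% reports$primaryid)
  pt_rows <- reac |>
    filter(.data$primaryid %in% reports$primaryid) |>
    distinct(.data$primaryid, .data$pt)

  # therapy start date for the PS drug: THER joined on dsg_drug_seq;
  # earliest full date wins, otherwise the first raw value in file order
  if (!is.null(tables$ther)) {
    ther <- as_tibble(tables$ther)
    names(ther) <- tolower(names(ther))
    ps_seq <- drug |>
      filter(.data$role_cod == "PS") |>
      select("primaryid", "drug_seq")
    ther_ps <- ther |>
      mutate(dsg_drug_seq = suppressWarnings(as.integer(.data$dsg_drug_seq))) |>
      inner_join(ps_seq, by = c("primaryid", "dsg_drug_seq" = "drug_seq"),
                 relationship = "many-to-many") |>
      mutate(.row = dplyr::row_number(),
             .date = parse_faers_date(.data$start_dt)) |>
      arrange(.data$primaryid, is.na(.data$.date), .data$.date, .data$.row) |>
      distinct(.data$primaryid, .keep_all = TRUE)
    reports <- reports |>
      select(-"start_dt") |>
      left_join(select(ther_ps, "primaryid", "start_dt"), by = "primaryid") |>
      mutate(start_dt = ifelse(is.na(.data$start_dt), "", .data$start_dt))
  }

  no_reaction <- setdiff(reports$primaryid, pt_rows$primaryid)
  reports <- filter(reports, !.data$primaryid %in% no_reaction)
  drug <- filter(drug, !.data$primaryid %in% no_reaction)

  rs <- report_set(reports, drug_rows = drug, pt_rows = pt_rows,
                   provenance = provenance)
  rs$log <- list(
    demo_exact_duplicate_rows = exact_demo_dups,
    demo_conflicting_primaryid_rows = conflicting,
    drug_orphan_rows = drug_orphans,
    reac_orphan_rows = reac_orphans,
    reports_without_reaction = length(no_reaction)
  )
  rs
}

#' Deduplicate case versions
#'
#' FAERS re-emits updated cases under new primaryids sharing the caseid.
#' Exact duplicate rows are collapsed at parse time; here, among several
#' primaryids sharing a caseid, only the numerically largest primaryid (the
#' latest case version) is retained. Idempotent.
#'
#' @param rs A `report_set`.
#' @return The deduplicated `report_set` (`dedup_applied = TRUE`); the number
#'   of removed versions is recorded in the log.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  keep <- rs$reports |>
    mutate(.pid_num = suppressWarnings(as.numeric(.data$primaryid))) |>
    arrange(.data$caseid, dplyr::desc(.data$.pid_num)) |>
    distinct(.data$caseid, .keep_all = TRUE) |>
    pull("primaryid")
  removed <- nrow(rs$reports) - length(keep)
  rs$reports <- filter(rs$reports, .data$primaryid %in% keep)
  rs$drug_rows <- filter(rs$drug_rows, .data$primaryid %in% keep)
  rs$pt_rows <- filter(rs$pt_rows, .data$primaryid %in% keep)
  rs$soc_rows <- filter(rs$soc_rows, .data$primaryid %in% keep)
  rs$dedup_applied <- TRUE
  rs$log$case_versions_removed <- removed
  rs
}

#' Default study-drug keyword lists
#'
#' Generic and product names for the two anti-amyloid antibodies, keyed by
#' canonical drug name.
#'
#' @return Named list of character vectors.
#' @export
default_study_keywords <- function() {
  list(
    lecanemab = c("lecanemab-irmb", "lecanemab", "leqembi"),
    aducanumab = c("aducanumab-avwa", "aducanumab", "aduhelm")
  )
}

#' Select reports whose primary-suspect drug matches study keywords
#'
#' A report is retained when any of its PS-role drug rows matches any keyword
#' case-insensitively as a substring of either `drugname` or `prodname`
#' (FAERS free-text drug names carry suffixes and dosage text). The matched
#' canonical drug name is written to `target_drug`. A report matching more
#' than one canonical drug is assigned to each (duplicated row, logged as
#' ambiguous); per-drug analyses count it once per drug.
#'
#' @param rs A `report_set`.
#' @param keywords Named list: canonical drug name -> character vector of
#'   keywords (see [default_study_keywords()]).
#' @return The filtered `report_set`.
#' @export
filter_primary_suspect <- function(rs, keywords = default_study_keywords()) {
  stopifnot(inherits(rs, "report_set"))
  if (length(keywords) == 0) abort("empty keyword list.")
  ps <- filter(rs$drug_rows, .data$role_cod == "PS")
  text <- tolower(paste(ifelse(is.na(ps$drugname), "", ps$drugname),
                        ifelse(is.na(ps$prodname), "", ps$prodname)))
  matches <- purrr::map(names(keywords), function(canon) {
    hit <- rep(FALSE, length(text))
    for (kw in keywords[[canon]]) {
      hit <- hit | grepl(tolower(kw), text, fixed = TRUE)
    }
    tibble(primaryid = ps$primaryid[hit], target_drug = canon)
  }) |>
    bind_rows() |>
    distinct()

  ambiguous <- matches |> count(.data$primaryid) |> filter(.data$n > 1)
  rs$reports <- rs$reports |>
    select(-"target_drug") |>
    inner_join(matches, by = "primaryid")
  keep <- unique(rs$reports$primaryid)
  rs$drug_rows <- filter(rs$drug_rows, .data$primaryid %in% keep)
  rs$pt_rows <- filter(rs$pt_rows, .data$primaryid %in% keep)
  rs$soc_rows <- filter(rs$soc_rows, .data$primaryid %in% keep)
  rs$log$ambiguous_target_reports <- nrow(ambiguous)
  rs
}

#' Reports not present in a target set (the comparator universe)
#'
#' @param rs The full deduplicated `report_set`.
#' @param target The target-drug `report_set` obtained from it.
#' @return A `report_set` containing the complement by primaryid.
#' @export
background_set <- function(rs, target) {
  stopifnot(inherits(rs, "report_set"), inherits(target, "report_set"))
  drop <- unique(target$reports$primaryid)
  rs$reports <- filter(rs$reports, !.data$primaryid %in% drop)
  keep <- rs$reports$primaryid
  rs$drug_rows <- filter(rs$drug_rows, .data$primaryid %in% keep)
  rs$pt_rows <- filter(rs$pt_rows, .data$primaryid %in% keep)
  rs$soc_rows <- filter(rs$soc_rows, .data$primaryid %in% keep)
  rs
}

#' Attach system organ classes to every report
#'
#' `socs` of a report is the union over its PTs of the dictionary's primary
#' SOC. PTs absent from the dictionary are collected in the log and excluded
#' from SOC-level counting, but remain available for PT-level counting.
#'
#' @param rs A `report_set`.
#' @param dictionary Tibble with columns `pt`, `soc`.
#' @return The `report_set` with `soc_rows` populated.
#' @export
map_meddra <- function(rs, dictionary) {
  stopifnot(inherits(rs, "report_set"))
  dictionary <- as_tibble(dictionary)
  if (nrow(dictionary) == 0) abort("empty PT to SOC dictionary.")
  dictionary <- generate_meddra_dictionary(dictionary)
  unmapped <- setdiff(unique(rs$pt_rows$pt), dictionary$pt)
  rs$soc_rows <- rs$pt_rows |>
    inner_join(dictionary, by = "pt") |>
    distinct(.data$primaryid, .data$soc)
  rs$mapped <- TRUE
  rs$log$unmapped_pts <- unmapped
  rs
}
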