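# Ground-truthed synthetic spontaneous-reporting database in the FAERS
# quarterly-file dialect. Reports are generated under drug-event independence
# except for configured planted (drug, PT) pairs whose per-report occurrence
# probability is multiplied by a known relative risk, so downstream signal
# detection can be scored against the truth.

draw_tto_days <- function(dist, n) {
  days <- switch(dist$family,
    lognormal = rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog),
    gamma = rgamma(n, shape = dist$shape, rate = dist$rate),
    abort(paste0("unknown time-to-onset family: ", dist$family))
  )
  pmax(0L, as.integer(round(days)))
}

# Blank out or truncate YYYYMMDD strings: FAERS carries missing dates as
# empty fields and partial dates as 4- or 6-digit strings.
corrupt_dates <- function(x, missing_rate, partial_rate) {
  u <- runif(length(x))
  x[u < missing_rate] <- ""
  part <- u >= missing_rate & u < missing_rate + partial_rate & x != ""
  width <- ifelse(runif(length(x)) < 0.5, 6L, 4L)
  x[part] <- substr(x[part], 1L, width[part])
  x
}

#' Generate a synthetic FAERS-dialect dataset with known ground truth
#'
#' Simulates `n_cases` spontaneous reports. Each report carries exactly one
#' primary-suspect (PS) drug, zero to two concomitant drugs, a PT set drawn
#' independently per PT at the background rate (multiplied by the planted
#' relative risk where the PS drug / PT pair is planted, probability clipped
#' to 1), demographics with configurable missingness, and event / therapy
#' start dates; time-to-onset is drawn per PS drug from the configured
#' distribution and the start date is back-computed from it. A configurable
#' fraction of cases is re-emitted under a larger primaryid with only the
#' mutable fields (reporter occupation, country) perturbed, emulating FAERS
#' case versioning.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_faers` object: a list with `tables` (tibbles `demo`,
#'   `drug`, `reac`, `ther` in the quarterly-file column layout), `manifest`
#'   (ground truth: planted signals, per-case PS drug and PT assignments,
#'   duplicate map, latest primaryid per case), and the `config`.
#' @seealso [write_synthetic_faers()] to serialise to '$'-delimited files,
#'   [parse_faers_tables()] to read them back.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_cases = 200, seed = 7))
#' head(ds$tables$demo)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  n <- config$n_cases
  drugs <- config$drugs
  pts <- config$pt_catalog$pt
  n_pt <- length(pts)

  caseid <- 1000000L + seq_len(n)
  ps_drug <- sample(drugs$drugname, n, replace = TRUE)

  # demographics
  sex <- ifelse(runif(n) < config$missing_sex_rate, "",
                ifelse(runif(n) < 0.57, "F", "M"))
  young <- runif(n) < 0.01
  age <- as.integer(round(ifelse(young, runif(n, 5, 17),
                                 pmin(100, pmax(18, rnorm(n, 75, 8))))))
  age_chr <- ifelse(runif(n) < config$missing_age_rate, "", as.character(age))
  age_cod <- ifelse(age_chr == "", "", "YR")
  occp <- sample(c("CN", "MD", "HP", "PH", ""), n, replace = TRUE,
                 prob = c(0.47, 0.31, 0.19, 0.02, 0.01))
  country <- sample(c("US", "JP", "FR", "IT", "CA", "CN", ""), n,
                    replace = TRUE,
                    prob = c(0.92, 0.03, 0.01, 0.01, 0.01, 0.01, 0.01))

  # event and therapy-start dates; start = event - time-to-onset
  win <- as.Date(config$date_window, format = "%Y%m%d")
  event_date <- win[1] + floor(runif(n) * (as.numeric(win[2] - win[1]) + 1))
  tto <- integer(n)
  for (d in unique(ps_drug)) {
    idx <- which(ps_drug == d)
    dist <- config$tto_distributions[[d]] %||% config$tto_distributions$.default
    tto[idx] <- draw_tto_days(dist, length(idx))
  }
  start_date <- event_date - tto
  event_dt <- corrupt_dates(format_faers_date(event_date),
                            config$missing_date_rate, config$partial_date_rate)
  start_dt <- corrupt_dates(format_faers_date(start_date),
                            config$missing_date_rate, config$partial_date_rate)

  # PT occurrence: independent Bernoulli per (report, PT) at the background
  # rate, scaled by the planted relative risk for the PS drug, clipped to 1.
  base_p <- min(1, config$background_pt_rate / n_pt)
  prob <- matrix(base_p, nrow = n, ncol = n_pt)
  if (nrow(config$planted_signals) > 0) {
    for (k in seq_len(nrow(config$planted_signals))) {
      sig <- config$planted_signals[k, ]
      j <- match(sig$pt, pts)
      rows <- ps_drug == sig$drug
      prob[rows, j] <- min(1, base_p * sig$rr)
    }
  }
  hit <- matrix(runif(n * n_pt), nrow = n) < prob
  none <- which(rowSums(hit) == 0L)
  if (length(none)) {
    # a FAERS case always carries at least one reaction
    forced <- sample.int(n_pt, length(none), replace = TRUE)
    hit[cbind(none, forced)] <- TRUE
  }
  pt_sets <- apply(hit, 1L, function(r) pts[r], simplify = FALSE)

  # concomitant (non-PS) drugs, uniform over the universe minus the PS drug
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  con_report <- rep(seq_len(n), n_con)
  con_drug <- sample(drugs$drugname, length(con_report), replace = TRUE)
  clash <- which(con_drug == ps_drug[con_report])
  while (length(clash)) {
    con_drug[clash] <- sample(drugs$drugname, length(clash), replace = TRUE)
    clash <- clash[con_drug[clash] == ps_drug[con_report[clash]]]
  }
  con_role <- sample(c("C", "SS", "I"), length(con_report), replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))

  # case versioning: duplicated cases are re-emitted under a larger
  # primaryid with only reporter occupation and country perturbed
  is_dup <- runif(n) < config$duplicate_rate
  n_versions <- ifelse(is_dup, 2L + rbinom(n, 1L, 0.1), 1L)
  version_of <- rep(seq_len(n), n_versions)
  version_no <- sequence(n_versions)
  primaryid <- caseid[version_of] * 100L + version_no
  is_latest <- version_no == n_versions[version_of]
  occp_v <- occp[version_of]
  country_v <- country[version_of]
  redraw <- version_no > 1L
  occp_v[redraw] <- sample(c("CN", "MD", "HP", "PH"), sum(redraw),
                           replace = TRUE)
  country_v[redraw] <- sample(c("US", "JP", "FR", "DE"), sum(redraw),
                              replace = TRUE)

  prodname_of <- setNames(drugs$prodname, drugs$drugname)

  demo <- tibble(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid[version_of]),
    event_dt = event_dt[version_of],
    sex = sex[version_of],
    age = age_chr[version_of],
    age_cod = age_cod[version_of],
    occp_cod = occp_v,
    occr_country = country_v
  )

  rep_id <- function(x) x[version_of]
  drug_rows <- bind_rows(
    tibble(report = seq_len(n), drug_seq = 1L, role_cod = "PS",
           drugname = ps_drug),
    tibble(report = con_report,
           drug_seq = unlist(lapply(n_con[n_con > 0], function(k) 1L + seq_len(k))),
           role_cod = con_role, drugname = con_drug)
  )
  # expand drug rows across case versions
  ver_by_report <- split(seq_along(version_of), version_of)
  expand_idx <- rep(seq_len(nrow(drug_rows)),
                    lengths(ver_by_report)[drug_rows$report])
  ver_idx <- unlist(ver_by_report[drug_rows$report], use.names = FALSE)
  drug <- tibble(
    primaryid = as.character(primaryid[ver_idx]),
    drug_seq = drug_rows$drug_seq[expand_idx],
    role_cod = drug_rows$role_cod[expand_idx],
    drugname = toupper(drug_rows$drugname[expand_idx]),
    prodname = toupper(unname(prodname_of[drug_rows$drugname[expand_idx]]))
  ) |>
    arrange(.data$primaryid, .data$drug_seq)

  reac_rows <- tibble(report = rep(seq_len(n), lengths(pt_sets)),
                      pt = unlist(pt_sets, use.names = FALSE))
  rexpand <- rep(seq_len(nrow(reac_rows)),
                 lengths(ver_by_report)[reac_rows$report])
  rver <- unlist(ver_by_report[reac_rows$report], use.names = FALSE)
  reac <- tibble(
    primaryid = as.character(primaryid[rver]),
    pt = reac_rows$pt[rexpand]
  ) |>
    arrange(.data$primaryid, .data$pt)

  ther <- tibble(
    primaryid = as.character(primaryid),
    dsg_drug_seq = 1L,
    start_dt = rep_id(start_dt)
  ) |>
    arrange(.data$primaryid)

  demo <- arrange(demo, .data$primaryid)

  dup_map <- split(as.character(primaryid), as.character(caseid[version_of]))
  dup_map <- dup_map[lengths(dup_map) > 1L]

  manifest <- list(
    planted_signals = config$planted_signals,
    cases = tibble(
      caseid = as.character(.env$caseid),
      primaryid_latest = as.character(.env$caseid * 100L + n_versions),
      ps_drug = ps_drug,
      sex = sex,
      tto_days = tto,
      pts = pt_sets
    ),
    duplicate_map = dup_map
  )

  structure(
    list(tables = list(demo = demo, drug = drug, reac = reac, ther = ther),
         manifest = manifest, config = config),
    class = "synthetic_faers"
  )
}

#' @export
print.synthetic_faers <- function(x, ...) {
  cat("<synthetic_faers>\n")
  cat("  cases:", nrow(x$manifest$cases),
      "| primaryids:", nrow(x$tables$demo),
      "| REAC rows:", nrow(x$tables$reac), "\n")
  invisible(x)
}

#' Derive the PT to SOC dictionary from a synthetic configuration
#'
#' Stands in for the licensed MedDRA dictionary: every catalog PT maps to
#' exactly one SOC. Conflicting duplicate mappings are a configuration error
#' (caught at [synthetic_config()] time and re-checked here).
#'
#' @param config A [synthetic_config()], or a bare tibble with `pt`, `soc`.
#' @return A tibble with columns `pt`, `soc`, one row per PT.
#' @export
generate_meddra_dictionary <- function(config) {
  catalog <- if (inherits(config, "synthetic_config")) config$pt_catalog
             else as_tibble(config)
  if (nrow(catalog) == 0) abort("empty PT catalog.")
  catalog <- distinct(catalog, .data$pt, .data$soc)
  conflicts <- count(catalog, .data$pt) |> filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("PT mapped to conflicting SOCs: ",
                 paste(conflicts$pt, collapse = ", ")))
  }
  catalog
}

#' Write synthetic tables to FAERS-dialect files
#'
#' Emits one '$'-delimited UTF-8 file per table (DEMO.txt, DRUG.txt,
#' REAC.txt, THER.txt) with a header line, plus the ground-truth manifest as
#' JSON. Identical input yields byte-identical files.
#'
#' @param x A `synthetic_faers` object from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths (elements
#'   `demo`, `drug`, `reac`, `ther`, `manifest`).
#' @export
write_synthetic_faers <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_faers"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             ther = file.path(dir, "THER.txt"))
  for (nm in names(paths)) {
    readr::write_delim(x$tables[[nm]], paths[nm], delim = "$", na = "")
  }
  manifest <- x$manifest
  manifest$cases$pts <- lapply(manifest$cases$pts, identity)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = FALSE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}

#' Write / read a PT to SOC dictionary as two-column tab-delimited text
#'
#' @param dictionary A tibble with columns `pt`, `soc`.
#' @param path File path.
#' @return `write_meddra_dictionary()` returns the path invisibly;
#'   `read_meddra_dictionary()` returns the dictionary tibble.
#' @export
write_meddra_dictionary <- function(dictionary, path) {
  dictionary <- generate_meddra_dictionary(dictionary)
  readr::write_tsv(dictionary, path)
  invisible(path)
}

#' @rdname write_meddra_dictionary
#' @export
read_meddra_dictionary <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  generate_meddra_dictionary(d)
}
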