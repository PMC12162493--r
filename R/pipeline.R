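# One reproducible run: simulate (or read) -> ingest -> dedup -> filter ->
# map -> descriptive table -> SOC & PT screening per drug -> sex-stratified
# log-ROR matrix with clustering order -> time-to-onset summary and group
# comparison -> manifest. All randomness flows from the run seed.

#' Configuration of a pipeline run
#'
#' Exactly one of `input_paths` (FAERS-dialect files on disk) or `synthetic`
#' (a [synthetic_config()]) must be given.
#'
#' @param input_paths Named list of file paths (`demo`, `drug`, `reac`,
#'   `ther`, `meddra`) or NULL.
#' @param synthetic A [synthetic_config()] or NULL; its seed is overridden
#'   by `seed`.
#' @param keywords Canonical-drug keyword lists (see
#'   [default_study_keywords()]).
#' @param min_a PT-level screening threshold (the shared `a >= 3`
#'   criterion); SOC screening keeps all observed SOCs.
#' @param z,z_ebgm Interval quantiles (default 1.96).
#' @param thresholds Named list of positivity-threshold overrides for
#'   [disproportionality_stats()] (`ror_lower_min`, `prr_min`, `chisq_min`,
#'   `ic025_min`, `ebgm05_min`).
#' @param log_base Base of the stratum-matrix log transform.
#' @param stratify Run the sex-stratified analysis?
#' @param tto_extraction_date Plausibility bound for onset dates.
#' @param outdir Output directory.
#' @param figures Also render PNG figures (heatmap via pheatmap if
#'   installed, time-to-onset boxplot via ggplot2)?
#' @param seed Integer master seed.
#' @return A `faers_run_config` list.
#' @export
faers_run_config <- function(input_paths = NULL, synthetic = NULL,
                             keywords = default_study_keywords(),
                             min_a = 3, z = 1.96, z_ebgm = 1.96,
                             thresholds = list(),
                             log_base = 10, stratify = TRUE,
                             tto_extraction_date = "20240630",
                             outdir = tempfile("faersignal-run-"),
                             figures = FALSE,
                             seed = 1L) {
  if (is.null(input_paths) == is.null(synthetic)) {
    abort("exactly one of `input_paths` or `synthetic` must be set.")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (length(keywords) == 0) abort("empty keyword list.")
  thr <- utils::modifyList(
    list(ror_lower_min = 1, prr_min = 2, chisq_min = 4,
         ic025_min = 0, ebgm05_min = 2),
    thresholds
  )
  if (any(unlist(thr) < 0)) abort("thresholds must be non-negative.")
  if (min_a < 0) abort("`min_a` must be non-negative.")
  structure(
    list(input_paths = input_paths, synthetic = synthetic,
         keywords = keywords, min_a = min_a, z = z, z_ebgm = z_ebgm,
         thresholds = thr, log_base = log_base, stratify = stratify,
         tto_extraction_date = tto_extraction_date,
         outdir = outdir, figures = figures, seed = as.integer(seed)),
    class = "faers_run_config"
  )
}

#' Execute the full pipeline
#'
#' Runs every stage in order and writes the run artifacts under
#' `cfg$outdir`: the descriptive table, per-drug SOC and PT signal tables,
#' the stratum log-ROR matrix with clustering orders, time-to-onset
#' summaries and group comparisons, and a JSON run manifest with the config
#' hash, seed, thresholds and per-stage report counts. Identical config and
#' seed reproduce identical artifacts.
#'
#' @param cfg A [faers_run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`report_sets`,
#'   `descriptive`, `soc_signals`, `pt_signals`, `stratified`, `matrix`,
#'   `tto`, `manifest`) and `paths` of the files written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "faers_run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage_counts <- list()
  thr <- cfg$thresholds

  # --- acquire data ---------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    syn_cfg <- cfg$synthetic
    syn_cfg$seed <- cfg$seed
    ds <- generate_dataset(syn_cfg)
    data_dir <- file.path(cfg$outdir, "data")
    paths$data <- write_synthetic_faers(ds, data_dir)
    dictionary <- generate_meddra_dictionary(syn_cfg)
    rs <- parse_faers_tables(ds)
  } else {
    dict_path <- cfg$input_paths$meddra
    if (is.null(dict_path)) abort("`input_paths` needs a `meddra` entry.")
    dictionary <- read_meddra_dictionary(dict_path)
    rs <- parse_faers_tables(cfg$input_paths[
      intersect(c("demo", "drug", "reac", "ther"), names(cfg$input_paths))])
  }
  stage_counts$parsed <- n_reports(rs)

  # --- dedup, filter, map ---------------------------------------------
  rs <- deduplicate(rs)
  stage_counts$deduplicated <- n_reports(rs)
  rs <- map_meddra(rs, dictionary)
  target <- filter_primary_suspect(rs, cfg$keywords)
  background <- background_set(rs, target)
  stage_counts$target_reports <- n_reports(target)
  stage_counts$background_reports <- n_reports(background)

  # --- descriptive table ----------------------------------------------
  descriptive <- descriptive_summary(target)
  paths$descriptive <- file.path(cfg$outdir, "descriptive_summary.csv")
  readr::write_csv(descriptive, paths$descriptive)

  # --- SOC and PT screening per drug ----------------------------------
  drugs <- sort(unique(stats::na.omit(target$reports$target_drug)))
  stat_args <- c(list(z = cfg$z, z_ebgm = cfg$z_ebgm, min_a = cfg$min_a), thr)
  soc_signals <- list(); pt_signals <- list()
  for (d in drugs) {
    soc_tabs <- enumerate_tables(target, background, d, level = "SOC",
                                 stratum = "overall", min_a = 1)
    pt_tabs <- enumerate_tables(target, background, d, level = "PT",
                                stratum = "overall", min_a = cfg$min_a)
    soc_signals[[d]] <- do.call(screen_signals, c(list(soc_tabs), stat_args))
    pt_signals[[d]] <- do.call(screen_signals, c(list(pt_tabs), stat_args))
    paths[[paste0("soc_", d)]] <-
      file.path(cfg$outdir, paste0("signals_soc_", d, ".csv"))
    paths[[paste0("pt_", d)]] <-
      file.path(cfg$outdir, paste0("signals_pt_", d, ".csv"))
    readr::write_csv(soc_signals[[d]], paths[[paste0("soc_", d)]])
    readr::write_csv(pt_signals[[d]], paths[[paste0("pt_", d)]])
  }

  # --- sex-stratified log-ROR matrix ----------------------------------
  stratified <- NULL; mat <- NULL
  if (isTRUE(cfg$stratify)) {
    stratified <- do.call(stratified_signals,
                          c(list(target, background, drugs = drugs), stat_args))
    mat <- tryCatch(
      cluster_order(log_ror_matrix(stratified, base = cfg$log_base)),
      error = function(e) {
        warn(paste0("stratum matrix skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(mat)) {
      paths$matrix <- file.path(cfg$outdir, "stratum_log_ror_matrix.csv")
      write_stratum_matrix(mat, paths$matrix)
      if (isTRUE(cfg$figures)) {
        paths$heatmap <- render_heatmap(mat, file.path(cfg$outdir,
                                                       "stratum_heatmap.png"))
      }
    }
  }

  # --- time-to-onset ---------------------------------------------------
  records <- compute_tto(target, extraction_date = cfg$tto_extraction_date)
  tto_by_drug <- tto_summary(records, "drug")
  tto_by_drug_sex <- tto_summary(records, "drug_sex")
  comparisons <- list()
  for (d in drugs) {
    f <- records$tto_days[records$exclusion_reason == "none" &
                            records$drug == d & records$sex %in% "F"]
    m <- records$tto_days[records$exclusion_reason == "none" &
                            records$drug == d & records$sex %in% "M"]
    if (length(f) && length(m)) {
      comparisons[[d]] <- mutate(compare_tto(f, m), drug = d,
                                 contrast = "F vs M")
    }
  }
  comparisons <- bind_rows(comparisons)
  paths$tto_records <- file.path(cfg$outdir, "tto_records.csv")
  paths$tto_summary <- file.path(cfg$outdir, "tto_summary.csv")
  readr::write_csv(records, paths$tto_records)
  readr::write_csv(bind_rows(
    mutate(tto_by_drug, sex = NA_character_), tto_by_drug_sex),
    paths$tto_summary)
  if (nrow(comparisons)) {
    paths$tto_tests <- file.path(cfg$outdir, "tto_tests.csv")
    readr::write_csv(comparisons, paths$tto_tests)
  }
  if (isTRUE(cfg$figures)) {
    paths$tto_figure <- render_tto_figure(records,
                                          file.path(cfg$outdir, "tto.png"))
  }

  # --- manifest --------------------------------------------------------
  cfg_for_hash <- cfg
  cfg_for_hash$outdir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg_for_hash),
    thresholds = thr,
    min_a = cfg$min_a, z = cfg$z, z_ebgm = cfg$z_ebgm,
    log_base = cfg$log_base,
    stage_counts = stage_counts,
    ingest_log = rs$log
  )
  paths$manifest <- file.path(cfg$outdir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    report_sets = list(all = rs, target = target, background = background),
    descriptive = descriptive,
    soc_signals = soc_signals, pt_signals = pt_signals,
    stratified = stratified, matrix = mat,
    tto = list(records = records, by_drug = tto_by_drug,
               by_drug_sex = tto_by_drug_sex, tests = comparisons),
    manifest = manifest, paths = paths
  ))
}

render_heatmap <- function(mat, path) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    warn("pheatmap not installed; heatmap figure skipped.")
    return(NULL)
  }
  grDevices::png(path, width = 900, height = 200 + 22 * nrow(mat$matrix),
                 res = 110)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(mat$matrix, clustering_method = "average",
                     cluster_rows = nrow(mat$matrix) > 1, cluster_cols = TRUE)
  path
}

render_tto_figure <- function(records, path) {
  df <- filter(records, .data$exclusion_reason == "none", !is.na(.data$sex))
  if (nrow(df) == 0) return(NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$drug, y = .data$tto_days,
                                        fill = .data$sex)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "time to onset (days)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 110)
  path
}

#' Render a human-readable Markdown report from run artifacts
#'
#' Assembles the descriptive table, the per-drug signal tables (two-decimal
#' formatted columns), the stratum matrix and the time-to-onset summary into
#' one Markdown document. Missing artifacts are marked absent, not fatal.
#'
#' @param artifacts The list returned by [run_pipeline()].
#' @param path Output file (default `report.md` in the run directory).
#' @return The path, invisibly.
#' @export
render_report <- function(artifacts, path = NULL) {
  path <- path %||% file.path(dirname(artifacts$paths$manifest), "report.md")
  md_table <- function(df, cols = names(df)) {
    df <- df[, intersect(cols, names(df)), drop = FALSE]
    if (nrow(df) == 0) return("*(empty)*")
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1L, function(r)
      paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |"))
    paste(c(hdr, sep, body), collapse = "\n")
  }
  section <- function(title, content) paste0("## ", title, "\n\n", content)
  absent <- "*artifact absent*"

  parts <- c("# Disproportionality analysis report", "")
  parts <- c(parts, section("Descriptive characteristics",
    if (is.null(artifacts$descriptive)) absent else
      md_table(artifacts$descriptive)))
  sig_cols <- c("term", "frequency", "ror_ci", "prr_chisq", "ebgm_ebgm05",
                "ic_ic025", "consensus_positive")
  for (d in names(artifacts$soc_signals %||% list())) {
    parts <- c(parts, section(paste0("SOC-level signals: ", d),
                              md_table(artifacts$soc_signals[[d]], sig_cols)))
  }
  for (d in names(artifacts$pt_signals %||% list())) {
    tb <- artifacts$pt_signals[[d]]
    n_pos <- sum(tb$consensus_positive, na.rm = TRUE)
    parts <- c(parts, section(
      paste0("PT-level signals: ", d),
      paste0(n_pos, " consensus-positive PT signal",
             if (n_pos == 1) "" else "s", ".\n\n",
             md_table(tb, sig_cols))))
  }
  parts <- c(parts, section("Sex-stratified log-ROR matrix",
    if (is.null(artifacts$matrix)) absent else {
      m <- artifacts$matrix
      md_table(as_tibble(round(m$matrix[m$row_order, m$col_order,
                                        drop = FALSE], 2),
                         rownames = "pt"))
    }))
  parts <- c(parts, section("Time-to-onset",
    if (is.null(artifacts$tto)) absent else paste0(
      md_table(mutate(artifacts$tto$by_drug_sex,
                      dplyr::across(dplyr::where(is.numeric), ~round(.x, 1)))),
      "\n\n",
      if (nrow(artifacts$tto$tests %||% tibble()) > 0)
        md_table(mutate(artifacts$tto$tests,
                        p_value = signif(.data$p_value, 3)))
      else "")))
  writeLines(paste(parts, collapse = "\n\n"), path)
  invisible(path)
}
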