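test_that("parsing joins tables into one report per primaryid", {
  rs <- parse_faers_tables(fixture_raw_tables())
  expect_s3_class(rs, "report_set")
  expect_equal(n_reports(rs), 5)
  # duplicate REAC PT rows collapse to a set
  r1002 <- rs$pt_rows$pt[rs$pt_rows$primaryid == "1002"]
  expect_equal(r1002, "Headache")
  # THER start date joined via dsg_drug_seq to the PS drug
  expect_equal(rs$reports$start_dt[rs$reports$primaryid == "1002"],
               "20230108")
  # age in months normalised to years
  expect_equal(rs$reports$age_years[rs$reports$primaryid == "2001"],
               828 / 12)
  expect_true(is.na(rs$reports$sex[rs$reports$primaryid == "3001"]))
})

test_that("parser round-trips the generator against its manifest", {
  ds <- generate_dataset(small_config(n_cases = 50, seed = 5,
                                      duplicate_rate = 0,
                                      missing_date_rate = 0,
                                      partial_date_rate = 0))
  dir <- file.path(tempdir(), "roundtrip")
  paths <- write_synthetic_faers(ds, dir)
  rs <- parse_faers_tables(paths[c("demo", "drug", "reac", "ther")])
  expect_equal(n_reports(rs), 50)
  cases <- ds$manifest$cases
  for (i in seq_len(nrow(cases))) {
    pid <- cases$primaryid_latest[i]
    expect_setequal(rs$pt_rows$pt[rs$pt_rows$primaryid == pid],
                    cases$pts[[i]])
  }
  unlink(dir, recursive = TRUE)
})

test_that("orphan DRUG/REAC rows are dropped and counted, not fatal", {
  tabs <- fixture_raw_tables()
  tabs$drug <- dplyr::bind_rows(tabs$drug, tibble::tibble(
    primaryid = "9999", drug_seq = "1", role_cod = "PS",
    drugname = "GHOST", prodname = "GHOST"))
  tabs$reac <- dplyr::bind_rows(tabs$reac, tibble::tibble(
    primaryid = "9999", pt = "Headache"))
  rs <- parse_faers_tables(tabs)
  expect_equal(n_reports(rs), 5)
  expect_equal(rs$log$drug_orphan_rows, 1)
  expect_equal(rs$log$reac_orphan_rows, 1)
})

test_that("missing mandatory table errors; THER is optional", {
  tabs <- fixture_raw_tables()
  expect_error(parse_faers_tables(tabs[c("demo", "drug")]), "reac")
  rs <- parse_faers_tables(tabs[c("demo", "drug", "reac")])
  expect_true(all(rs$reports$start_dt %in% c("", NA_character_)))
})

test_that("deduplication keeps the numerically largest primaryid per case", {
  rs <- parse_faers_tables(fixture_raw_tables())
  rs <- deduplicate(rs)
  expect_false("1001" %in% rs$reports$primaryid)
  expect_true("1002" %in% rs$reports$primaryid)
  expect_false(anyDuplicated(rs$reports$caseid) > 0)
  expect_true(rs$dedup_applied)
  expect_equal(rs$log$case_versions_removed, 1)
})

test_that("deduplication is idempotent and matches the generator manifest", {
  ds <- generate_dataset(small_config(n_cases = 300, seed = 8,
                                      duplicate_rate = 0.4))
  rs <- parse_faers_tables(ds)
  d1 <- deduplicate(rs)
  d2 <- deduplicate(d1)
  expect_identical(d1$reports, d2$reports)
  expect_setequal(d1$reports$primaryid, ds$manifest$cases$primaryid_latest)
})

test_that("exact duplicate raw rows collapse to one record", {
  tabs <- fixture_raw_tables()
  tabs$demo <- dplyr::bind_rows(tabs$demo, tabs$demo[1, ])
  rs <- parse_faers_tables(tabs)
  expect_equal(sum(rs$reports$primaryid == "1001"), 1)
  expect_equal(rs$log$demo_exact_duplicate_rows, 1)
})

test_that("primary-suspect keyword filter applies role and name rules", {
  rs <- deduplicate(parse_faers_tables(fixture_raw_tables()))
  f <- filter_primary_suspect(rs)
  # PS prodname LEQEMBI -> lecanemab
  expect_equal(f$reports$target_drug[f$reports$primaryid == "1002"],
               "lecanemab")
  # PS drugname ADUCANUMAB-AVWA -> aducanumab
  expect_equal(f$reports$target_drug[f$reports$primaryid == "2001"],
               "aducanumab")
  # keyword drug present with role C only -> excluded
  expect_false("3001" %in% f$reports$primaryid)
  # non-keyword PS drug -> excluded
  expect_false("4001" %in% f$reports$primaryid)
  expect_error(filter_primary_suspect(rs, list()), "empty keyword")
})

test_that("filter is a subset and commutes with dedup on generator data", {
  ds <- generate_dataset(small_config(n_cases = 400, seed = 17,
                                      duplicate_rate = 0.2))
  rs <- parse_faers_tables(ds)
  a <- filter_primary_suspect(deduplicate(rs))
  b <- deduplicate(filter_primary_suspect(rs))
  expect_setequal(a$reports$primaryid, b$reports$primaryid)
  expect_true(all(a$reports$primaryid %in% rs$reports$primaryid))
  # target assignment matches the manifest's PS drug
  truth <- ds$manifest$cases
  joined <- dplyr::inner_join(a$reports,
                              truth, by = c("primaryid" = "primaryid_latest"))
  expect_true(all(joined$target_drug == joined$ps_drug))
})

test_that("SOC mapping takes the union over PTs and logs unmapped PTs", {
  rs <- deduplicate(parse_faers_tables(fixture_raw_tables()))
  rs <- map_meddra(rs, fixture_dictionary())
  # report 2001 has Chills + Headache in two different SOCs
  socs_2001 <- rs$soc_rows$soc[rs$soc_rows$primaryid == "2001"]
  expect_setequal(socs_2001, c("Nervous system disorders",
                               "General disorders"))
  # two PTs sharing one SOC collapse to one element
  dict2 <- tibble::tibble(pt = c("Chills", "Headache"),
                          soc = "Nervous system disorders")
  rs2 <- map_meddra(rs, dict2)
  expect_equal(rs2$soc_rows$soc[rs2$soc_rows$primaryid == "2001"],
               "Nervous system disorders")
  # Rash is not in the dictionary: kept at PT level, absent at SOC level
  expect_true("Rash" %in% rs$pt_rows$pt)
  expect_false("4001" %in% rs$soc_rows$primaryid)
  expect_true("Rash" %in% rs$log$unmapped_pts)
  expect_error(map_meddra(rs, fixture_dictionary()[0, ]), "empty")
})

test_that("descriptive summary reproduces printed share arithmetic", {
  # report counts as published: 892 + 517 = 1409 with 747 F / 568 M / 94 NA
  n_lec <- 892; n_adu <- 517
  sex <- c(rep("F", 747), rep("M", 568), rep(NA_character_, 94))
  reports <- tibble::tibble(
    primaryid = as.character(seq_len(n_lec + n_adu)),
    caseid = as.character(seq_len(n_lec + n_adu)),
    sex = sex,
    target_drug = c(rep("lecanemab", n_lec), rep("aducanumab", n_adu))
  )
  rs <- report_set(reports, dedup_applied = TRUE)
  ds <- descriptive_summary(rs)
  share <- function(char, cat, drug)
    ds$pct[ds$characteristic == char & ds$category == cat & ds$drug == drug]
  expect_equal(share("drug", "lecanemab", "overall"), 63.31)
  expect_equal(share("drug", "aducanumab", "overall"), 36.69)
  expect_equal(share("sex", "Female", "overall"), 53.02)
  expect_equal(share("sex", "Male", "overall"), 40.31)
  expect_equal(share("sex", "Missing", "overall"), 6.67)
})

test_that("descriptive percentage blocks sum to 100 within rounding", {
  ds0 <- generate_dataset(small_config(n_cases = 600, seed = 23))
  rs <- map_meddra(deduplicate(parse_faers_tables(ds0)),
                   generate_meddra_dictionary(small_config()))
  tgt <- filter_primary_suspect(rs)
  ds <- descriptive_summary(tgt)
  sums <- ds |>
    dplyr::summarise(s = sum(pct), .by = c(characteristic, drug))
  expect_true(all(abs(sums$s - 100) <= 0.05))
})

test_that("single-sex input yields a 100% category", {
  reports <- tibble::tibble(primaryid = as.character(1:10),
                            caseid = as.character(1:10),
                            sex = "F", target_drug = "lecanemab")
  ds <- descriptive_summary(report_set(reports, dedup_applied = TRUE))
  expect_equal(ds$pct[ds$characteristic == "sex" & ds$drug == "overall" &
                        ds$category == "Female"], 100)
  expect_warning(descriptive_summary(report_set(reports[0, ])), "no reports")
})
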