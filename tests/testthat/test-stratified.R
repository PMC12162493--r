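# Hand-built strata: drugA with a male-only PT strong enough to clear all
# four criteria in the male stratum (a=8, b=5, c=4, d=195).
make_stratified_fixture <- function() {
  tgt_reports <- tibble::tibble(
    primaryid = sprintf("t%02d", 1:15),
    caseid = sprintf("ct%02d", 1:15),
    sex = c(rep("M", 12), "F", "F", NA),
    target_drug = "drugA"
  )
  tgt_pts <- tibble::tibble(
    primaryid = sprintf("t%02d", 1:15),
    pt = c(rep("Tinnitus", 8), rep("Headache", 4), "Headache", "Headache",
           "Tinnitus")
  )
  bg_reports <- tibble::tibble(
    primaryid = sprintf("b%03d", 1:400),
    caseid = sprintf("cb%03d", 1:400),
    sex = rep(c("M", "F"), 200),
    target_drug = NA_character_
  )
  # 5 male and 2 female background Tinnitus reports; the rest split
  # between Headache and Nausea
  bg_pt <- rep(c("Headache", "Nausea"), each = 200)
  bg_pt[c(1, 3, 5, 7, 9)] <- "Tinnitus"   # males
  bg_pt[c(2, 4)] <- "Tinnitus"            # females
  bg_pts <- tibble::tibble(primaryid = sprintf("b%03d", 1:400), pt = bg_pt)
  list(
    target = report_set(tgt_reports, pt_rows = tgt_pts,
                        dedup_applied = TRUE),
    background = report_set(bg_reports, pt_rows = bg_pts,
                            dedup_applied = TRUE)
  )
}

test_that("a male-only PT appears in the male stratum only and missing-sex
           reports contribute to no stratum", {
  fx <- make_stratified_fixture()
  strata <- stratified_signals(fx$target, fx$background)
  expect_named(strata, c("drugA-F", "drugA-M"))
  expect_false("Tinnitus" %in% strata[["drugA-F"]]$term)
  expect_true("Tinnitus" %in% strata[["drugA-M"]]$term)
  m <- strata[["drugA-M"]]
  # 8 male Tinnitus reports, not 9: the missing-sex report is excluded
  expect_equal(m$frequency[m$term == "Tinnitus"], 8)
  expect_true(m$consensus_positive[m$term == "Tinnitus"])
})

test_that("log-ROR matrix applies the zero-substitution and log rules", {
  fx <- make_stratified_fixture()
  strata <- stratified_signals(fx$target, fx$background)
  mat <- log_ror_matrix(strata)
  expect_true(all(is.finite(mat$matrix)))
  expect_true("Tinnitus" %in% rownames(mat$matrix))
  # Tinnitus has a = 0 among female target reports: ROR -> 0.01 -> -2
  expect_equal(unname(mat$matrix["Tinnitus", "drugA-F"]), -2)
  # male stratum: ROR = (8*195)/(5*4) = 78
  expect_equal(unname(mat$matrix["Tinnitus", "drugA-M"]), log10(78))
})

test_that("log transform maps ROR 1 to 0, ROR 100 to 2, and falls back to
           the Haldane correction for infinite RORs", {
  tb <- tibble::tibble(
    term = c("X", "Y", "Z"), frequency = c(5, 5, 5), b = c(5, 1, 0),
    c = c(5, 5, 5), d = c(5, 100, 100),
    ror = c(1, 100, NA), consensus_positive = c(TRUE, TRUE, TRUE)
  )
  mat <- log_ror_matrix(list(s1 = tb))
  expect_equal(unname(mat$matrix["X", "s1"]), 0)
  expect_equal(unname(mat$matrix["Y", "s1"]), 2)
  # a=5, b=0: undefined ROR with a > 0 -> (5.5*100.5)/(0.5*5.5)
  expect_equal(unname(mat$matrix["Z", "s1"]),
               log10((5.5 * 100.5) / (0.5 * 5.5)))
  expect_error(log_ror_matrix(list(s1 = tb[0, ])), "no consensus-positive")
})

test_that("clustering order is deterministic, permutation-invariant, and
           places identical rows adjacently", {
  m0 <- matrix(c(1, 1, 0, 0,
                 0, 0, 2, 2,
                 1, 1, 0, 0,
                 5, 4, 5, 4,
                 0.1, 0, 2, 2,
                 5, 5, 4, 4),
               nrow = 6, byrow = TRUE,
               dimnames = list(paste0("PT", 1:6), paste0("S", 1:4)))
  sm <- structure(list(matrix = m0, row_order = 1:6, col_order = 1:4,
                       base = 10, row_hclust = NULL, col_hclust = NULL),
                  class = "stratum_matrix")
  c1 <- cluster_order(sm)
  expect_setequal(c1$row_order, 1:6)
  # identical rows PT1/PT3 are adjacent leaves
  pos <- match(c(1, 3), c1$row_order)
  expect_equal(abs(diff(pos)), 1)
  # rerun: identical leaf order
  c2 <- cluster_order(sm)
  expect_identical(c1$row_order, c2$row_order)
  # permuting input rows leaves the leaf label sequence unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  smp <- sm
  smp$matrix <- m0[perm, ]
  smp$row_order <- 1:6
  c3 <- cluster_order(smp)
  expect_identical(rownames(c1$matrix)[c1$row_order],
                   rownames(c3$matrix)[c3$row_order])
})

test_that("a single-row matrix keeps the identity order", {
  m1 <- structure(list(matrix = matrix(1:4, nrow = 1,
                                       dimnames = list("PT1",
                                                       paste0("S", 1:4))),
                       row_order = 1L, col_order = 1:4, base = 10,
                       row_hclust = NULL, col_hclust = NULL),
                  class = "stratum_matrix")
  c1 <- cluster_order(m1)
  expect_equal(c1$row_order, 1L)
})

test_that("stratum matrix exports with leaf orders", {
  fx <- make_stratified_fixture()
  mat <- cluster_order(log_ror_matrix(stratified_signals(fx$target,
                                                         fx$background)))
  path <- tempfile(fileext = ".csv")
  paths <- write_stratum_matrix(mat, path)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$pt, rownames(mat$matrix))
  unlink(paths)
})
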