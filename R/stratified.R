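# Sex-stratified PT-level screening and the log-ROR matrix behind the
# cluster heatmap: rows are the union of consensus-positive PTs over the
# drug-by-sex strata, columns the strata, values log10(ROR) with the
# zero-substitution rule (ROR of 0, i.e. a = 0 in the stratum, is replaced
# by 0.01 before the log, giving exactly -2).

#' PT-level signal screening within each drug-by-sex stratum
#'
#' For every combination of target drug and sex (`F`, `M`), restricts both
#' the target and the background sets to that sex (the standard stratified
#' construction) and screens all PTs observed for the drug in the stratum.
#' Reports with missing sex contribute to no stratum.
#'
#' @param target Filtered `report_set` (reports carry `target_drug`).
#' @param background Comparator `report_set`.
#' @param drugs Canonical drug names; defaults to those present in `target`.
#' @param min_a Minimum stratum case count for a PT to be screened. The
#'   default 1 keeps sub-threshold PTs visible so the matrix can show a
#'   valid ROR for a PT that is positive only in a sibling stratum.
#' @param ... Threshold overrides passed to [screen_signals()].
#' @return Named list of screened signal tibbles, names `"<drug>-F"`,
#'   `"<drug>-M"`. Empty strata yield empty tibbles with a warning.
#' @export
stratified_signals <- function(target, background, drugs = NULL,
                               min_a = 1, ...) {
  drugs <- drugs %||% sort(unique(stats::na.omit(target$reports$target_drug)))
  combos <- expand.grid(drug = drugs, sex = c("F", "M"),
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  names(out) <- paste0(combos$drug, "-", combos$sex)
  for (i in seq_len(nrow(combos))) {
    tabs <- enumerate_tables(target, background, combos$drug[i],
                             level = "PT", stratum = combos$sex[i],
                             min_a = min_a)
    if (nrow(tabs) == 0) {
      warn(paste0("empty stratum: ", names(out)[i]))
    }
    out[[i]] <- screen_signals(tabs, ...)
  }
  out
}

#' Assemble the stratum log-ROR matrix
#'
#' Rows are the union of PTs consensus-positive in at least one stratum;
#' columns are the strata. Each cell is `log(ROR, base)` of the stratum's
#' point estimate. An ROR of 0 - in particular a PT with `a = 0` in the
#' stratum, including PTs never observed there - is replaced by 0.01 before
#' the log (so base 10 gives exactly -2). An infinite ROR (a > 0 with a
#' zero background cell) is recomputed with the Haldane-Anscombe +0.5
#' correction on all four cells so every cell of the matrix is finite.
#'
#' @param stratum_tables Named list from [stratified_signals()].
#' @param base Logarithm base (default 10).
#' @param zero_value Substitute for a zero ROR (default 0.01).
#' @return A `stratum_matrix`: list with `matrix` (PT x stratum, finite),
#'   `row_order`, `col_order` (identity until [cluster_order()] is applied),
#'   `base`.
#' @export
log_ror_matrix <- function(stratum_tables, base = 10, zero_value = 0.01) {
  stopifnot(is.list(stratum_tables), length(stratum_tables) > 0)
  positive <- lapply(stratum_tables, function(tb) {
    if (nrow(tb) == 0) character() else tb$term[tb$consensus_positive]
  })
  rows <- sort(unique(unlist(positive)))
  if (length(rows) == 0) {
    abort("no consensus-positive PT in any stratum; nothing to plot.")
  }
  cols <- names(stratum_tables)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  for (j in seq_along(cols)) {
    tb <- stratum_tables[[j]]
    for (i in seq_along(rows)) {
      k <- if (nrow(tb)) match(rows[i], tb$term) else NA_integer_
      if (is.na(k) || tb$frequency[k] == 0) {
        val <- zero_value
      } else {
        val <- tb$ror[k]
        if (is.na(val) || !is.finite(val)) {
          aa <- tb$frequency[k]; bb <- tb$b[k]; cc <- tb$c[k]; dd <- tb$d[k]
          if (aa == 0) {
            val <- zero_value
          } else {
            # infinite/undefined with a > 0: Haldane-Anscombe correction
            val <- ((aa + 0.5) * (dd + 0.5)) / ((bb + 0.5) * (cc + 0.5))
          }
        }
      }
      m[i, j] <- log(val, base = base)
    }
  }
  stopifnot(all(is.finite(m)))
  structure(
    list(matrix = m, row_order = seq_along(rows), col_order = seq_along(cols),
         base = base, row_hclust = NULL, col_hclust = NULL),
    class = "stratum_matrix"
  )
}

#' @export
print.stratum_matrix <- function(x, ...) {
  cat("<stratum_matrix>", nrow(x$matrix), "PTs x", ncol(x$matrix),
      "strata (log base", x$base, ")\n")
  print(head(x$matrix[x$row_order, x$col_order, drop = FALSE], 10))
  invisible(x)
}

order_one_axis <- function(m) {
  if (nrow(m) < 2) {
    return(list(order = seq_len(nrow(m)), hclust = NULL))
  }
  # sort by label first so the dendrogram (and its ties) never depend on
  # the caller's row order
  lab <- rownames(m)
  srt <- order(lab)
  hc <- hclust(dist(m[srt, , drop = FALSE], method = "euclidean"),
               method = "average")
  list(order = match(lab[srt][hc$order], lab), hclust = hc)
}

#' Hierarchical clustering order for the stratum matrix
#'
#' Agglomerative clustering (Euclidean distance, average linkage) on rows
#' and columns. Rows are pre-sorted by label so ties break deterministically
#' and permuting the input row order cannot change the dendrogram. A single
#' row (or column) keeps the identity order.
#'
#' @param m A `stratum_matrix` from [log_ror_matrix()].
#' @return The matrix object with `row_order` / `col_order` set to leaf
#'   orders and the `hclust` objects attached.
#' @export
cluster_order <- function(m) {
  stopifnot(inherits(m, "stratum_matrix"))
  r <- order_one_axis(m$matrix)
  co <- order_one_axis(t(m$matrix))
  m$row_order <- r$order
  m$col_order <- co$order
  m$row_hclust <- r$hclust
  m$col_hclust <- co$hclust
  m
}

#' Export a stratum matrix as delimited text
#'
#' Writes the matrix with row labels plus the two leaf orders.
#'
#' @param m A `stratum_matrix`.
#' @param path CSV path for the matrix; orders go to `<path>.orders.csv`.
#' @return Invisibly, the paths written.
#' @export
write_stratum_matrix <- function(m, path) {
  stopifnot(inherits(m, "stratum_matrix"))
  df <- as_tibble(m$matrix, rownames = "pt")
  readr::write_csv(df, path)
  orders <- tibble(
    axis = c(rep("row", length(m$row_order)),
             rep("col", length(m$col_order))),
    position = c(seq_along(m$row_order), seq_along(m$col_order)),
    index = c(m$row_order, m$col_order),
    label = c(rownames(m$matrix)[m$row_order],
              colnames(m$matrix)[m$col_order])
  )
  opath <- paste0(path, ".orders.csv")
  readr::write_csv(orders, opath)
  invisible(c(path, opath))
}
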