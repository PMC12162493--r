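# Demographic summary of the filtered report set (per target drug and
# overall), with explicit Missing categories.

age_band <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "Missing",
    age < 18 ~ "<18",
    age < 65 ~ "18–64.9",
    age <= 85 ~ "65–85",
    .default = ">85"
  )
}

sex_label <- function(sex) {
  dplyr::case_when(sex == "F" ~ "Female", sex == "M" ~ "Male",
                   .default = "Missing")
}

reporter_label <- function(x) {
  dplyr::case_when(
    x == "consumer" ~ "Consumer",
    x == "health-professional" ~ "Health-professional",
    x == "physician" ~ "Physician",
    x == "pharmacist" ~ "Pharmacist",
    .default = "Missing"
  )
}

count_block <- function(df, characteristic, category) {
  df |>
    mutate(category = category) |>
    count(.data$drug, .data$category) |>
    mutate(characteristic = characteristic)
}

#' Demographic summary table
#'
#' Per-drug and overall counts with percentages for the report share per
#' drug, sex, age band (<18, 18–64.9, 65–85, >85), reporter type
#' and reporter country. Percentages are count / column total x 100, rounded
#' to two decimals; missing values are reported as their own category.
#'
#' @param rs A filtered `report_set` (reports carry `target_drug`).
#' @return A tibble with columns `characteristic`, `category`, `drug`
#'   (canonical drug names plus `"overall"`), `n`, `pct`. Within each
#'   characteristic and drug column the percentages sum to 100 up to
#'   rounding.
#' @export
descriptive_summary <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  df <- rs$reports |> filter(!is.na(.data$target_drug))
  if (nrow(df) == 0) {
    warn("no reports with a target drug; returning empty summary.")
    return(tibble(characteristic = character(), category = character(),
                  drug = character(), n = integer(), pct = numeric()))
  }
  df <- rename(df, drug = "target_drug")
  both <- bind_rows(df, mutate(df, drug = "overall"))

  drug_share <- df |>
    count(category = .data$drug) |>
    mutate(drug = "overall", characteristic = "drug")

  blocks <- bind_rows(
    drug_share,
    count_block(both, "sex", sex_label(both$sex)),
    count_block(both, "age", age_band(both$age_years)),
    count_block(both, "reporter_type", reporter_label(both$reporter_type)),
    count_block(both, "country",
                ifelse(is.na(both$country), "Missing", both$country))
  )

  totals <- count(both, .data$drug, name = "total")
  overall_total <- totals$total[totals$drug == "overall"]

  out <- blocks |>
    left_join(totals, by = "drug") |>
    mutate(
      # the per-drug share block is a share of the overall total
      total = ifelse(.data$characteristic == "drug", overall_total,
                     .data$total),
      pct = round(.data$n / .data$total * 100, 2)
    ) |>
    select("characteristic", "category", "drug", "n", "pct")

  # stable ordering: characteristic blocks, then drug columns, then size
  out |>
    mutate(characteristic = factor(.data$characteristic,
      levels = c("drug", "sex", "age", "reporter_type", "country"))) |>
    arrange(.data$characteristic, .data$drug, dplyr::desc(.data$n),
            .data$category) |>
    mutate(characteristic = as.character(.data$characteristic))
}
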