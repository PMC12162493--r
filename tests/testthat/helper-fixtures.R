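# Hand-built report sets and small synthetic configs shared across tests.

# Target drugX: r1 {Headache}, r2 {Nausea}, r5 {Headache, Nausea};
# background: r3 {Headache}, r4 {Nausea}.
fixture_five_reports <- function() {
  target <- report_set(
    tibble::tibble(primaryid = c("r1", "r2", "r5"),
                   caseid = c("c1", "c2", "c5"),
                   sex = c("F", "M", "F"),
                   target_drug = "drugX"),
    pt_rows = tibble::tibble(
      primaryid = c("r1", "r2", "r5", "r5"),
      pt = c("Headache", "Nausea", "Headache", "Nausea")),
    dedup_applied = TRUE
  )
  background <- report_set(
    tibble::tibble(primaryid = c("r3", "r4"),
                   caseid = c("c3", "c4"),
                   sex = c("F", "M"),
                   target_drug = NA_character_),
    pt_rows = tibble::tibble(primaryid = c("r3", "r4"),
                             pt = c("Headache", "Nausea")),
    dedup_applied = TRUE
  )
  list(target = target, background = background)
}

# A tiny raw-table fixture exercising dedup, roles, keywords and PT sets.
fixture_raw_tables <- function() {
  demo <- tibble::tibble(
    primaryid = c("1001", "1002", "2001", "3001", "4001"),
    caseid    = c("100",  "100",  "200",  "300",  "400"),
    event_dt  = c("20230210", "20230210", "202301", "", "20230601"),
    sex       = c("F", "F", "M", "", "M"),
    age       = c("75", "75", "828", "", "70"),
    age_cod   = c("YR", "YR", "MON", "", "YR"),
    occp_cod  = c("MD", "CN", "HP", "", "PH"),
    occr_country = c("US", "US", "JP", "", "US")
  )
  drug <- tibble::tibble(
    primaryid = c("1001", "1002", "2001", "2001", "3001", "4001"),
    drug_seq  = c("1", "1", "1", "2", "1", "1"),
    role_cod  = c("PS", "PS", "PS", "C", "C", "PS"),
    drugname  = c("LEQEMBI", "LEQEMBI", "ADUCANUMAB-AVWA", "LEQEMBI",
                  "LECANEMAB", "IBUPROFEN"),
    prodname  = c("LEQEMBI", "LEQEMBI", "ADUHELM", "LEQEMBI",
                  "LEQEMBI", "ADVIL")
  )
  reac <- tibble::tibble(
    primaryid = c("1001", "1002", "1002", "2001", "2001", "3001", "4001"),
    pt = c("Headache", "Headache", "Headache", "Chills", "Headache",
           "Nausea", "Rash")
  )
  ther <- tibble::tibble(
    primaryid = c("1002", "2001", "4001"),
    dsg_drug_seq = c("1", "1", "1"),
    start_dt = c("20230108", "20230101", "20230505")
  )
  list(demo = demo, drug = drug, reac = reac, ther = ther)
}

fixture_dictionary <- function() {
  tibble::tibble(
    pt = c("Headache", "Chills", "Nausea"),
    soc = c("Nervous system disorders", "General disorders",
            "Gastrointestinal disorders")
  )
}

# Small, fast generator config used in round-trip tests.
small_config <- function(n_cases = 400, seed = 1, ...) {
  synthetic_config(n_cases = n_cases, seed = seed, ...)
}
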