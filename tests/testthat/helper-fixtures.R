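# In-code fixture builders shared across test files.

demo_row <- function(primaryid, caseid = substr(primaryid, 1, nchar(primaryid) - 1L),
                     caseversion = 1L, fda_dt = as.Date("2020-06-01"),
                     event_dt = fda_dt - 10L, age = 60, age_cod = "YR",
                     sex = "M", occr_country = "US") {
  data.table::data.table(primaryid = primaryid, caseid = caseid,
                         caseversion = as.integer(caseversion),
                         fda_dt = fda_dt, event_dt = event_dt,
                         age = as.numeric(age), age_cod = age_cod,
                         sex = sex, occr_country = occr_country)
}

# build a deduplicated-case universe from per-case drug/event membership
# flags -- the enumeration oracle for contingency tables
cases_from_flags <- function(has_drug, has_event, role = "PS") {
  n <- length(has_drug)
  pid <- paste0(sprintf("%08d", seq_len(n)), "1")
  demo <- do.call(rbind, lapply(seq_len(n), function(i) demo_row(pid[i])))
  drug <- data.table::data.table(
    primaryid = pid, drug_seq = 1L,
    role_cod = role,
    drugname = ifelse(has_drug, "STUDYDRUG", "OTHERDRUG"),
    indi_pt = NA_character_)
  reac <- data.table::data.table(
    primaryid = pid,
    pt = ifelse(has_event, "Target event", "Other event"))
  ds <- faers_dataset(demo, drug, reac,
                      data.table::data.table(primaryid = character(),
                                             outc_cod = character()))
  deduplicate_cases(ds)
}

study_drug_query <- function(roles = c("PS", "SS")) {
  drug_query("STUDYDRUG", roles = roles)
}
target_event_query <- function() event_query("Target event")

# random valid DEMO records for round-trip fuzzing
random_demo <- function(n, seed = 1) {
  withr::with_seed(seed, {
    age <- sample(c(NA, 1:90), n, replace = TRUE)
    demo <- data.table::data.table(
      primaryid = paste0(sample(1e7:2e7, n), "1"),
      caseid = as.character(sample(1e7:2e7, n)),
      caseversion = sample(1:3, n, replace = TRUE),
      fda_dt = as.Date("2020-01-01") + sample(0:730, n, replace = TRUE),
      event_dt = as.Date("2020-01-01") + sample(0:700, n, replace = TRUE),
      age = as.numeric(age),
      age_cod = ifelse(is.na(age), NA_character_,
                       sample(c("YR", "DEC", "MON"), n, replace = TRUE)),
      sex = sample(c("M", "F", "UNK"), n, replace = TRUE),
      occr_country = sample(c("US", "GB", "JP", "FR"), n, replace = TRUE))
    demo$caseid <- substr(demo$primaryid, 1, nchar(demo$primaryid) - 1L)
    demo
  })
}

random_tables <- function(n, seed = 1, min_cell = 1L, max_cell = 200L) {
  withr::with_seed(seed, data.table::data.table(
    a = sample(min_cell:max_cell, n, TRUE),
    b = sample(min_cell:max_cell, n, TRUE),
    c = sample(min_cell:max_cell, n, TRUE),
    d = sample(min_cell:max_cell, n, TRUE)))
}
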