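test_that("parsing a DEMO file yields one typed record per data line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$sex$occr_country",
    "100000011$10000001$1$20200515$20200424$60$YR$M$US",
    "100000021$10000002$1$20211231$$6$DEC$F$GB"), f)
  dt <- read_faers_table(f, "DEMO")
  expect_equal(nrow(dt), 2L)
  expect_equal(dt$age, c(60, 6))
  expect_equal(dt$age_cod, c("YR", "DEC"))
  expect_equal(dt$fda_dt, as.Date(c("2020-05-15", "2021-12-31")))
  expect_true(is.na(dt$event_dt[2]))
  expect_identical(dt$caseversion, c(1L, 1L))
})

test_that("DRUG role codes map through unchanged and bad codes are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$drug_seq$role_cod$drugname",
               "100000011$1$PS$AVAPRITINIB",
               "100000011$2$C$LORATADINE",
               "100000021$1$XX$MYSTERY"), f)
  dt <- read_faers_table(f, "DRUG")
  expect_equal(dt$role_cod, c("PS", "C"))
  rej <- attr(dt, "rejects")
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "role_cod")
})

test_that("a header missing a required column is a schema error naming it", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid", "100000011$10000001"), f)
  expect_error(read_faers_table(f, "DEMO"), "caseversion")
  expect_error(read_faers_table(file.path(tempdir(), "nope.txt"), "DEMO"),
               "no such file")
})

test_that("lines with the wrong field count go to the rejects report, never both", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$pt",
               "100000011$Rash",
               "100000021$Rash$EXTRA$FIELDS",
               "100000031"), f)
  dt <- read_faers_table(f, "REAC")
  rej <- attr(dt, "rejects")
  expect_equal(nrow(dt), 1L)
  expect_equal(nrow(rej), 2L)
  expect_equal(attr(dt, "n_malformed"), 2L)
  # accepted and rejected sets are disjoint
  expect_length(intersect(dt$primaryid, sub("\\$.*", "", rej$content)), 0L)
})

test_that("write then parse is the identity on valid records", {
  demo <- random_demo(10, seed = 42)
  f <- withr::local_tempfile(fileext = ".txt")
  write_faers_table(demo, f, "DEMO")
  back <- read_faers_table(f, "DEMO")
  expect_equal(as.data.frame(back), as.data.frame(demo), ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "rejects")), 0L)
})

test_that("an empty record list writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_faers_table(random_demo(0), f, "DEMO")
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_faers_table(f, "DEMO")), 0L)
})

test_that("embedded delimiters are replaced by a space on write and survive re-parsing", {
  drug <- data.table::data.table(primaryid = "100000011", drug_seq = 1L,
                                 role_cod = "PS",
                                 drugname = "AVA$PRITINIB 300$MG")
  f <- withr::local_tempfile(fileext = ".txt")
  write_faers_table(drug, f, "DRUG")
  back <- read_faers_table(f, "DRUG")
  expect_equal(nrow(back), 1L)
  expect_equal(back$drugname, "AVA PRITINIB 300 MG")
  expect_equal(nrow(attr(back, "rejects")), 0L)
})

test_that("fuzzed records round-trip through a full dataset write/read", {
  demo <- random_demo(50, seed = 99)
  drug <- data.table::data.table(
    primaryid = demo$primaryid, drug_seq = 1L, role_cod = "PS",
    drugname = "STUDYDRUG", indi_pt = rep(c("Hypertension", NA), 25))
  reac <- data.table::data.table(primaryid = demo$primaryid, pt = "Rash")
  outc <- data.table::data.table(primaryid = demo$primaryid[1:5],
                                 outc_cod = c("DE", "LT", "HO", "OT", "RI"))
  ds <- faers_dataset(demo, drug, reac, outc)
  dir <- withr::local_tempdir()
  write_faers_dataset(ds, dir)
  back <- read_faers_dataset(dir)
  for (tab in c("demo", "drug", "reac", "outc")) {
    cols <- setdiff(names(ds[[tab]]), "quarter")
    expect_equal(as.data.frame(back[[tab]][, cols, with = FALSE]),
                 as.data.frame(ds[[tab]][, cols, with = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("orphan child rows are dropped with a logged count", {
  demo <- demo_row("100000011")
  drug <- data.table::data.table(primaryid = c("100000011", "999999991"),
                                 drug_seq = 1L, role_cod = "PS",
                                 drugname = "X", indi_pt = NA_character_)
  ds <- faers_dataset(demo, drug,
                      data.table::data.table(primaryid = character(), pt = character()),
                      data.table::data.table(primaryid = character(), outc_cod = character()))
  expect_equal(nrow(ds$drug), 1L)
  expect_equal(attr(ds, "log")$n_orphans_dropped, 1L)
})

test_that("window loading merges disjoint quarters and uses a closed interval", {
  dir <- withr::local_tempdir()
  q1 <- file.path(dir, "2020Q1"); q2 <- file.path(dir, "2020Q2")
  mk <- function(d, ids, dates) {
    demo <- data.table::rbindlist(Map(function(i, dt) demo_row(i, fda_dt = dt),
                                      ids, dates))
    ds <- faers_dataset(
      demo,
      data.table::data.table(primaryid = ids, drug_seq = 1L, role_cod = "PS",
                             drugname = "X", indi_pt = NA_character_),
      data.table::data.table(primaryid = ids, pt = "Rash"),
      data.table::data.table(primaryid = character(), outc_cod = character()))
    write_faers_dataset(ds, d)
  }
  mk(q1, c("100000011", "100000021"),
     as.Date(c("2020-01-15", "2020-02-20")))
  mk(q2, c("100000031", "100000041", "100000051"),
     as.Date(c("2020-04-01", "2020-05-10", "2020-06-30")))

  full <- load_faers_window(c(q1, q2), "2020-01-01", "2020-06-30")
  expect_equal(nrow(full$demo), 5L)  # disjoint union; end date inclusive
  expect_true("100000051" %in% full$demo$primaryid)

  part <- load_faers_window(c(q1, q2), "2020-01-01", "2020-05-10")
  expect_equal(nrow(part$demo), 4L)  # 06-30 outside; 05-10 on the boundary in
  expect_false("100000051" %in% part$demo$primaryid)

  expect_error(load_faers_window(c(q1, q2), "2020-12-31", "2020-01-01"),
               "window")
})

test_that("window loading is idempotent on its own merged output", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_cases = 300, seed = 11, duplicate_version_rate = 0)
  simulate_faers(cfg, dir = file.path(dir, "sim"), split_quarters = TRUE)
  qs <- list.dirs(file.path(dir, "sim"), recursive = FALSE)
  merged <- load_faers_window(qs, "2020-01-01", "2021-12-31")
  redir <- file.path(dir, "merged")
  write_faers_dataset(merged, redir)
  again <- load_faers_window(redir, "2020-01-01", "2021-12-31")
  data.table::setorder(merged$demo, primaryid)
  data.table::setorder(again$demo, primaryid)
  expect_equal(as.data.frame(again$demo), as.data.frame(merged$demo),
               ignore_attr = TRUE)
  expect_equal(nrow(again$drug), nrow(merged$drug))
  expect_equal(nrow(again$reac), nrow(merged$reac))
})
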