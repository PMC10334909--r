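#' FAERS quarterly-extract table schemas
#'
#' Column layout and types for the five ASCII tables of a FAERS Quarterly
#' Data Extract (QDE) as this package reads them.  Files are
#' dollar-delimited with a header line and no quoting.
#'
#' * `DEMO` — one row per report version: `primaryid`, `caseid`,
#'   `caseversion`, `fda_dt` (FDA receipt date), `event_dt`, `age`,
#'   `age_cod` (YR/DEC/MON/WK/DY/HR), `sex` (M/F/UNK), `occr_country`.
#' * `DRUG` — `primaryid`, `drug_seq`, `role_cod` (PS/SS/C/I), `drugname`.
#' * `REAC` — `primaryid`, `pt` (MedDRA preferred term).
#' * `OUTC` — `primaryid`, `outc_cod` (DE/LT/HO/DS/CA/RI/OT).
#' * `INDI` — `primaryid`, `indi_drug_seq`, `indi_pt`.
#'
#' @param kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"INDI"`.
#' @return a list with `columns` (character), `types` (named character:
#'   `"character"`, `"integer"`, `"numeric"`, `"date"`) and `codes`
#'   (named list of closed code sets).
#' @export
faers_schema <- function(kind = c("DEMO", "DRUG", "REAC", "OUTC", "INDI")) {
  kind <- match.arg(toupper(kind), c("DEMO", "DRUG", "REAC", "OUTC", "INDI"))
  switch(kind,
    DEMO = list(
      columns = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
                  "age", "age_cod", "sex", "occr_country"),
      types = c(primaryid = "character", caseid = "character",
                caseversion = "integer", fda_dt = "date", event_dt = "date",
                age = "numeric", age_cod = "character", sex = "character",
                occr_country = "character"),
      codes = list(age_cod = c("YR", "DEC", "MON", "WK", "DY", "HR"),
                   sex = c("M", "F", "UNK"))
    ),
    DRUG = list(
      columns = c("primaryid", "drug_seq", "role_cod", "drugname"),
      types = c(primaryid = "character", drug_seq = "integer",
                role_cod = "character", drugname = "character"),
      codes = list(role_cod = c("PS", "SS", "C", "I"))
    ),
    REAC = list(
      columns = c("primaryid", "pt"),
      types = c(primaryid = "character", pt = "character"),
      codes = list()
    ),
    OUTC = list(
      columns = c("primaryid", "outc_cod"),
      types = c(primaryid = "character", outc_cod = "character"),
      codes = list(outc_cod = c("DE", "LT", "HO", "DS", "CA", "RI", "OT"))
    ),
    INDI = list(
      columns = c("primaryid", "indi_drug_seq", "indi_pt"),
      types = c(primaryid = "character", indi_drug_seq = "integer",
                indi_pt = "character"),
      codes = list()
    )
  )
}

FAERS_DELIM <- "$"

#' Read one FAERS quarterly ASCII table
#'
#' Parses a dollar-delimited QDE table into a typed `data.table`.  Lines
#' whose field count differs from the header, or whose coded fields fall
#' outside the table's closed code set, are diverted to a rejects report
#' (attribute `"rejects"`) rather than silently dropped.  Bytes that are not
#' valid UTF-8 are replaced.
#'
#' @param path file path.
#' @param kind table kind, see [faers_schema()].
#' @return a `data.table` with the schema's columns and types; attributes
#'   `"rejects"` (a `data.table` with `line`, `content`, `reason`) and
#'   `"n_malformed"`.
#' @export
read_faers_table <- function(path, kind) {
  schema <- faers_schema(kind)
  if (!file.exists(path)) stop("cannot read FAERS table: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- iconv(lines, "UTF-8", "UTF-8", sub = "?")
  if (length(lines) == 0L) stop("empty file (no header line): ", path)

  header <- strsplit(lines[[1L]], FAERS_DELIM, fixed = TRUE)[[1L]]
  header <- tolower(squish(header))
  missing_cols <- setdiff(schema$columns, header)
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s header is missing required column(s): %s",
                 kind, paste(missing_cols, collapse = ", ")))
  }

  body <- lines[-1L]
  body <- body[nzchar(body)]
  # field count per line; strsplit drops trailing empties, so count separators
  nfield <- nchar(body) - nchar(gsub(FAERS_DELIM, "", body, fixed = TRUE)) + 1L
  ok <- nfield == length(header)
  rejects <- data.table::data.table(
    line = which(!ok) + 1L,
    content = body[!ok],
    reason = sprintf("expected %d fields, found %d", length(header), nfield[!ok])
  )
  good <- body[ok]

  if (length(good) == 0L) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character()), length(header)), header))
  } else {
    dt <- data.table::fread(
      text = paste(c(lines[[1L]], good), collapse = "\n"),
      sep = FAERS_DELIM, quote = "", header = TRUE,
      colClasses = "character", na.strings = NULL, strip.white = FALSE,
      showProgress = FALSE)
    data.table::setnames(dt, tolower(squish(names(dt))))
  }
  dt <- dt[, schema$columns, with = FALSE]

  # coded fields outside their closed sets are row-level rejects
  bad_code <- rep(FALSE, nrow(dt))
  reason <- rep(NA_character_, nrow(dt))
  for (col in names(schema$codes)) {
    v <- toupper(squish(dt[[col]]))
    data.table::set(dt, j = col, value = v)
    bad <- !(v %in% c(schema$codes[[col]], "")) & !is.na(v)
    reason[bad & !bad_code] <- sprintf("invalid %s code", col)
    bad_code <- bad_code | bad
  }
  if (any(bad_code)) {
    line_of_good <- (which(ok) + 1L)[seq_len(nrow(dt))]
    rejects <- rbind(rejects, data.table::data.table(
      line = line_of_good[bad_code],
      content = good[bad_code],
      reason = reason[bad_code]))
    dt <- dt[!bad_code]
  }

  dt <- type_faers_columns(dt, schema)
  data.table::setattr(dt, "rejects", rejects[order(line)])
  data.table::setattr(dt, "n_malformed", nrow(rejects))
  dt[]
}

type_faers_columns <- function(dt, schema) {
  for (col in schema$columns) {
    v <- dt[[col]]
    v[!is.na(v) & v == ""] <- NA_character_
    v <- switch(schema$types[[col]],
      character = v,
      integer = suppressWarnings(as.integer(v)),
      numeric = suppressWarnings(as.numeric(v)),
      date = parse_faers_date(v))
    data.table::set(dt, j = col, value = v)
  }
  # a report age is interpretable only with its unit: drop half-specified pairs
  if (all(c("age", "age_cod") %in% names(dt))) {
    half <- xor(is.na(dt$age), is.na(dt$age_cod))
    if (any(half)) {
      data.table::set(dt, which(half), "age", NA_real_)
      data.table::set(dt, which(half), "age_cod", NA_character_)
    }
  }
  dt
}

#' Write one FAERS quarterly ASCII table
#'
#' Inverse of [read_faers_table()]: `read_faers_table(write_faers_table(x))`
#' returns `x` for any valid table.  FAERS files carry no quoting, so a
#' delimiter or newline occurring inside a free-text field is replaced by a
#' space before writing.
#'
#' @param x `data.table`/`data.frame` with the schema's columns.
#' @param path output path.
#' @param kind table kind, see [faers_schema()].
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, kind) {
  schema <- faers_schema(kind)
  missing_cols <- setdiff(schema$columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.table::as.data.table(x)[, schema$columns, with = FALSE]
  for (col in schema$columns) {
    v <- out[[col]]
    v <- switch(schema$types[[col]],
      date = format_faers_date(v),
      as.character(v))
    v[is.na(v)] <- ""
    v <- gsub("[$\r\n]", " ", v)
    data.table::set(out, j = col, value = v)
  }
  data.table::fwrite(out, path, sep = FAERS_DELIM, quote = FALSE,
                     col.names = TRUE, showProgress = FALSE)
  invisible(path)
}

#' Bundle the five FAERS tables into one dataset object
#'
#' Enforces the parent/child invariant: every `primaryid` in the DRUG, REAC
#' and OUTC tables must appear in DEMO; orphan child rows cannot form a case
#' and are dropped with a logged count (attribute `"log"`).
#'
#' @param demo,drug,reac,outc typed `data.table`s as returned by
#'   [read_faers_table()] (the in-memory `drug` table may carry the folded
#'   `indi_pt` column).
#' @param quarter optional quarter label (e.g. `"2020Q1"`) recorded on each
#'   DEMO row; defaults to the quarter of `fda_dt`.
#' @return an object of class `faers_dataset`: a list with elements `demo`,
#'   `drug`, `reac`, `outc`.
#' @export
faers_dataset <- function(demo, drug, reac, outc, quarter = NULL) {
  demo <- data.table::as.data.table(demo)
  drug <- data.table::as.data.table(drug)
  reac <- data.table::as.data.table(reac)
  outc <- data.table::as.data.table(outc)
  if (!"indi_pt" %in% names(drug)) drug[, "indi_pt" := NA_character_]
  if (!"quarter" %in% names(demo)) {
    demo[, "quarter" := if (is.null(quarter)) quarter_label(demo$fda_dt)
         else quarter]
  }
  n_orphan <- 0L
  for (nm in c("drug", "reac", "outc")) {
    tab <- get(nm)
    orphan <- !(tab$primaryid %in% demo$primaryid)
    n_orphan <- n_orphan + sum(orphan)
    assign(nm, tab[!orphan])
  }
  ds <- structure(list(demo = demo, drug = drug, reac = reac, outc = outc),
                  class = "faers_dataset")
  attr(ds, "log") <- list(n_orphans_dropped = n_orphan)
  ds
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("<faers_dataset>\n")
  cat(sprintf("  reports: %d  drug rows: %d  reaction rows: %d  outcome rows: %d\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$outc)))
  qs <- sort(unique(stats::na.omit(x$demo$quarter)))
  if (length(qs)) cat("  quarters:", paste(qs, collapse = ", "), "\n")
  invisible(x)
}

locate_faers_file <- function(dir, prefix) {
  hits <- list.files(dir, pattern = paste0("^", prefix, ".*\\.(txt|TXT)$"),
                     ignore.case = TRUE, full.names = TRUE)
  if (length(hits) == 0L) return(NULL)
  sort(hits)[[1L]]
}

#' Read one quarterly file set (a directory of FAERS tables)
#'
#' Expects files named `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`, `OUTC*.txt`
#' and optionally `INDI*.txt` (case-insensitive).  INDI rows are folded
#' into the drug table's `indi_pt` column where they join on
#' `primaryid` + `drug_seq`; unjoinable INDI rows are counted in the log.
#'
#' @param dir directory containing one quarter's tables.
#' @param quarter quarter label; defaults to a `20YYQn` token in the
#'   directory name, else the quarter of each report's receipt date.
#' @return a [faers_dataset()].
#' @export
read_faers_dataset <- function(dir, quarter = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  paths <- lapply(c(DEMO = "demo", DRUG = "drug", REAC = "reac", OUTC = "outc"),
                  function(p) locate_faers_file(dir, p))
  absent <- names(paths)[vapply(paths, is.null, logical(1))]
  if (length(absent)) {
    stop("quarterly file set ", dir, " is missing table(s): ",
         paste(absent, collapse = ", "))
  }
  tabs <- mapply(read_faers_table, paths, names(paths), SIMPLIFY = FALSE)

  indi_path <- locate_faers_file(dir, "indi")
  n_unjoined_indi <- 0L
  if (!is.null(indi_path)) {
    indi <- read_faers_table(indi_path, "INDI")
    joinable <- indi[!is.na(indi_drug_seq)]
    drug <- tabs$DRUG
    drug[joinable, "indi_pt" := i.indi_pt,
         on = c(primaryid = "primaryid", drug_seq = "indi_drug_seq")]
    matched <- joinable[drug, on = c(primaryid = "primaryid",
                                     indi_drug_seq = "drug_seq"),
                        nomatch = NULL]
    n_unjoined_indi <- nrow(indi) - nrow(matched)
    if (n_unjoined_indi > 0L) {
      message(sprintf("%d INDI row(s) in %s had no matching drug row; ignored",
                      n_unjoined_indi, dir))
    }
    tabs$DRUG <- drug
  }

  if (is.null(quarter)) {
    m <- regmatches(basename(dir), regexpr("20[0-9]{2}[Qq][1-4]", basename(dir)))
    if (length(m)) quarter <- toupper(m)
  }
  ds <- faers_dataset(tabs$DEMO, tabs$DRUG, tabs$REAC, tabs$OUTC,
                      quarter = quarter)
  lg <- attr(ds, "log")
  lg$n_unjoined_indi <- n_unjoined_indi
  lg$n_malformed <- sum(vapply(tabs, function(t) attr(t, "n_malformed"),
                               integer(1)))
  lg$rejects <- data.table::rbindlist(
    lapply(tabs, attr, "rejects"), idcol = "table")
  attr(ds, "log") <- lg
  ds
}

#' Write a dataset back out as a FAERS quarterly file set
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt` and `INDI.txt`
#' (indications are unfolded from the drug table) in the same
#' dollar-delimited dialect [read_faers_dataset()] reads.
#'
#' @param ds a [faers_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_faers_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "faers_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_faers_table(ds$demo, file.path(dir, "DEMO.txt"), "DEMO")
  write_faers_table(ds$drug, file.path(dir, "DRUG.txt"), "DRUG")
  write_faers_table(ds$reac, file.path(dir, "REAC.txt"), "REAC")
  write_faers_table(ds$outc, file.path(dir, "OUTC.txt"), "OUTC")
  indi <- data.table::as.data.table(ds$drug)[!is.na(indi_pt),
    list(primaryid, indi_drug_seq = drug_seq, indi_pt)]
  write_faers_table(indi, file.path(dir, "INDI.txt"), "INDI")
  invisible(dir)
}

#' Load and merge quarterly file sets over a reporting window
#'
#' Reads each quarterly directory, drops duplicate `primaryid` rows within a
#' quarter (first occurrence kept, count logged), merges all quarters, and
#' restricts to reports whose date lies in the closed interval
#' `[start, end]`.  The same `primaryid` may legitimately recur across
#' quarters (report versions); version resolution is the job of
#' [deduplicate_cases()], not of loading.
#'
#' @param dirs character vector of quarterly file-set directories.
#' @param start,end window bounds (`Date` or `"YYYY-MM-DD"`), both inclusive.
#' @param date_field which DEMO date defines the window: `"fda_dt"` (FDA
#'   receipt date, the conventional FAERS windowing field) or `"event_dt"`.
#' @return a merged [faers_dataset()]; quarter provenance is kept in the
#'   DEMO `quarter` column.
#' @export
load_faers_window <- function(dirs, start, end, date_field = c("fda_dt", "event_dt")) {
  date_field <- match.arg(date_field)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid window: start must be on or before end")
  }
  sets <- lapply(dirs, read_faers_dataset)
  n_dup_within <- 0L
  for (i in seq_along(sets)) {
    demo <- sets[[i]]$demo
    dup <- duplicated(demo$primaryid)
    n_dup_within <- n_dup_within + sum(dup)
    sets[[i]]$demo <- demo[!dup]
  }
  if (n_dup_within > 0L) {
    message(sprintf("%d duplicate primaryid row(s) within a quarter; kept first",
                    n_dup_within))
  }
  demo <- data.table::rbindlist(lapply(sets, `[[`, "demo"), use.names = TRUE)
  keep <- !is.na(demo[[date_field]]) &
    demo[[date_field]] >= start & demo[[date_field]] <= end
  demo <- demo[keep]
  ds <- faers_dataset(
    demo,
    data.table::rbindlist(lapply(sets, `[[`, "drug"), use.names = TRUE),
    data.table::rbindlist(lapply(sets, `[[`, "reac"), use.names = TRUE),
    data.table::rbindlist(lapply(sets, `[[`, "outc"), use.names = TRUE),
    quarter = demo$quarter)
  lg <- attr(ds, "log")
  lg$n_dup_primaryid_within_quarter <- n_dup_within
  lg$n_outside_window <- sum(!keep)
  attr(ds, "log") <- lg
  ds
}
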