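#' Default run configuration
#'
#' Mirrors the reference analysis: FAERS window 2020-01-01 to 2021-12-31
#' (FDA receipt date, closed on both ends), drug AVAPRITINIB/AYVAKIT as
#' suspect (PS/SS), MedDRA preferred term "Photosensitivity reaction",
#' Yates-corrected chi-square, minimum 3 co-reporting cases for screening.
#'
#' @return a named list understood by [run_signal_pipeline()].
#' @export
default_run_config <- function() {
  list(
    input_dirs = NULL,          # character vector of quarterly file sets
    use_fixture = FALSE,        # TRUE: analyze make_avapritinib_fixture()
    fixture_prr_match = FALSE,
    window_start = "2020-01-01",
    window_end = "2021-12-31",
    date_field = "fda_dt",
    drug_names = c("AVAPRITINIB", "AYVAKIT"),
    drug_match = "exact",
    drug_roles = c("PS", "SS"),
    event_terms = "Photosensitivity reaction",
    yates = TRUE,
    min_a = 3,
    out_dir = NULL,
    seed = 1L
  )
}

#' Read a run configuration file
#'
#' A flat YAML file whose keys override [default_run_config()]; unknown
#' keys are an error (they are usually typos).
#'
#' @param path YAML file path.
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Run the full disproportionality pipeline
#'
#' Loads the quarterly extracts (or the built-in reconstructed universe),
#' deduplicates cases, builds the drug-event 2x2 table, computes the
#' disproportionality statistics and criteria verdicts, and summarizes the
#' case-series demographics.  When `cfg$out_dir` is set, writes
#' `contingency.csv`, `signal.csv`, `signal.json`, `table1.csv` and
#' `run_log.txt`; every number in the rendered outputs is taken from the
#' returned typed objects, never recomputed.
#'
#' @param cfg configuration list, see [default_run_config()].
#' @return (invisibly) list with `cases`, `table` (`faers_2x2`), `signal`
#'   (`faers_signal`), `table1` (`faers_table1`), `log` (character).
#' @export
run_signal_pipeline <- function(cfg = default_run_config()) {
  logline <- character()
  say <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    message(msg)
  }

  if (isTRUE(cfg$use_fixture)) {
    ds <- make_avapritinib_fixture(prr_match = isTRUE(cfg$fixture_prr_match))
    say("input: built-in reconstructed universe (%d reports)", nrow(ds$demo))
  } else {
    if (is.null(cfg$input_dirs)) {
      stop("config: either input_dirs or use_fixture = TRUE is required")
    }
    ds <- load_faers_window(cfg$input_dirs, cfg$window_start, cfg$window_end,
                            date_field = cfg$date_field)
    lg <- attr(ds, "log")
    say("input: %d report(s) in window %s..%s from %d file set(s)",
        nrow(ds$demo), cfg$window_start, cfg$window_end, length(cfg$input_dirs))
    say("dropped: %d orphan child row(s), %d malformed line(s), %d outside window",
        lg$n_orphans_dropped, lg$n_malformed %||% 0L, lg$n_outside_window)
  }

  cases <- deduplicate_cases(ds)
  say("deduplicated: %d case(s); %d duplicate version(s) removed",
      nrow(cases$demo), cases$n_duplicates_removed)

  dq <- drug_query(cfg$drug_names, match = cfg$drug_match, roles = cfg$drug_roles)
  eq <- event_query(cfg$event_terms)
  sel <- case_has_drug(cases, dq) & case_has_event(cases, eq)
  say("drug+event cases: %d", sum(sel))
  if (sum(sel) == 0L) {
    stop("no cases match both the drug and the event query; no statistics emitted")
  }

  tab <- build_contingency(cases, dq, eq)
  sig <- disproportionality(tab, yates = isTRUE(cfg$yates),
                            min_events = cfg$min_a)
  t1 <- summarize_demographics(cases, dq, eq)
  say("PRR %.3f | chi2 %.2f | ROR %.3f (%.3f-%.3f) | IC %.3f | IC025 %.3f",
      sig$prr, sig$chi2, sig$ror, sig$ror_lower, sig$ror_upper, sig$ic, sig$ic025)
  say("criteria: evans=%s ror_rule=%s ic_rule=%s all_three=%s",
      sig$criteria$evans, sig$criteria$ror_rule, sig$criteria$ic_rule,
      sig$criteria$all_three)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(
      data.table::data.table(cell = c("a", "b", "c", "d", "n"),
                             count = c(tab$a, tab$b, tab$c, tab$d, tab$n)),
      file.path(cfg$out_dir, "contingency.csv"))
    sig_dt <- as.data.table.faers_signal(sig)
    data.table::fwrite(sig_dt, file.path(cfg$out_dir, "signal.csv"))
    jsonlite::write_json(as.list(sig_dt), file.path(cfg$out_dir, "signal.json"),
                         auto_unbox = TRUE, digits = NA)
    data.table::fwrite(as.data.table.faers_table1(t1),
                       file.path(cfg$out_dir, "table1.csv"))
    writeLines(logline, file.path(cfg$out_dir, "run_log.txt"))
  }
  invisible(list(cases = cases, table = tab, signal = sig, table1 = t1,
                 log = logline))
}
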