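#' Collapse versioned reports into deduplicated cases
#'
#' A FAERS case (`caseid`) may appear as several report versions
#' (`caseversion`), e.g. an initial report followed by follow-ups.  Counting
#' must be per case, so one version is retained per `caseid`: the highest
#' `caseversion`, ties broken by the latest FDA receipt date, then by the
#' lexicographically greatest `primaryid`.  Child rows (drugs, reactions,
#' outcomes) are restricted to the retained versions.
#'
#' @param ds a [faers_dataset()].
#' @return an object of class `faers_cases`: a list with `demo` (one row per
#'   case, including the derived logical `serious` — `TRUE` iff the case has
#'   at least one outcome code among DE/LT/HO/DS/CA/RI/OT), `drug`, `reac`,
#'   `outc`, `n_input_reports` and `n_duplicates_removed`.
#' @export
deduplicate_cases <- function(ds) {
  stopifnot(inherits(ds, "faers_dataset"))
  demo <- data.table::copy(ds$demo)
  ord <- order(demo$caseid,
               -data.table::frank(demo$caseversion, ties.method = "dense"),
               -data.table::frank(demo$fda_dt, ties.method = "dense", na.last = FALSE),
               -data.table::frank(demo$primaryid, ties.method = "dense"))
  demo <- demo[ord]
  keep <- !duplicated(demo$caseid)
  chosen <- demo[keep]
  data.table::setkey(chosen, NULL)
  chosen <- chosen[order(caseid)]

  ids <- chosen$primaryid
  drug <- ds$drug[primaryid %in% ids]
  reac <- ds$reac[primaryid %in% ids]
  outc <- ds$outc[primaryid %in% ids]
  chosen[, "serious" := primaryid %in% outc$primaryid]

  structure(list(demo = chosen, drug = drug, reac = reac, outc = outc,
                 n_input_reports = nrow(ds$demo),
                 n_duplicates_removed = nrow(ds$demo) - nrow(chosen)),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases>\n")
  cat(sprintf("  cases: %d (from %d report versions; %d duplicate version(s) removed)\n",
              nrow(x$demo), x$n_input_reports, x$n_duplicates_removed))
  cat(sprintf("  serious: %d\n", sum(x$demo$serious)))
  invisible(x)
}

#' Default stop-list of trailing dosage-form tokens
#'
#' Tokens stripped from the end of a verbatim drug name by
#' [normalize_drugname()].  Purely numeric trailing tokens (strengths such
#' as "300") are always stripped as well.
#'
#' @return character vector of uppercase tokens.
#' @export
drugname_stoplist <- function() {
  c("MG", "MCG", "G", "ML", "TABLET", "TABLETS", "TAB", "TABS",
    "CAPSULE", "CAPSULES", "CAP", "CAPS", "SOLUTION", "SUSPENSION",
    "INJECTION", "ORAL", "FILM", "COATED", "FILM-COATED", "CREAM",
    "OINTMENT", "UNKNOWN")
}

#' Normalize a verbatim drug name
#'
#' Uppercases, trims, collapses internal whitespace, and strips trailing
#' dosage-form/strength tokens (`"300 MG"`, `"TABLETS"`, ...) so that the
#' same product reported with different verbatim strings matches one query
#' name.  Mapping trade names to generics is not done here — synonyms belong
#' in [drug_query()]'s name set.
#'
#' @param x character vector of raw drug names.
#' @param stoplist uppercase tokens to strip from the end; see
#'   [drugname_stoplist()].
#' @return normalized names; `NA` (flagged unmatched) where nothing remains.
#' @export
#' @examples
#' normalize_drugname(" avapritinib 300 MG ")  # "AVAPRITINIB"
normalize_drugname <- function(x, stoplist = drugname_stoplist()) {
  # names repeat heavily across reports: normalize each distinct string once
  ux <- unique(x)
  out <- toupper(squish(ux))
  strip_trailing <- function(s) {
    if (is.na(s)) return(NA_character_)
    toks <- strsplit(s, " ", fixed = TRUE)[[1L]]
    while (length(toks) > 0L &&
           (toks[length(toks)] %in% stoplist ||
            grepl("^[0-9][0-9.]*$", toks[length(toks)]))) {
      toks <- toks[-length(toks)]
    }
    paste(toks, collapse = " ")
  }
  out <- vapply(out, strip_trailing, character(1), USE.NAMES = FALSE)
  out[is.na(ux) | is.na(out) | !nzchar(out)] <- NA_character_
  out[match(x, ux)]
}

#' Define a drug of interest
#'
#' @param names character set of drug name synonyms (generic and trade,
#'   e.g. `c("AVAPRITINIB", "AYVAKIT")`); compared after
#'   [normalize_drugname()].
#' @param match `"exact"` — normalized equality; `"substring"` — a query
#'   name occurring anywhere in the normalized drug name.
#' @param roles FAERS role codes that qualify; suspect means
#'   `c("PS", "SS")` (primary and secondary suspect).
#' @return a `drug_query` object.
#' @export
drug_query <- function(names, match = c("exact", "substring"),
                       roles = c("PS", "SS")) {
  match <- match.arg(match)
  names <- toupper(squish(names))
  names <- names[nzchar(names)]
  roles <- match.arg(roles, c("PS", "SS", "C", "I"), several.ok = TRUE)
  if (length(names) == 0L) stop("drug_query needs at least one name")
  structure(list(names = unique(names), match = match, roles = unique(roles)),
            class = "drug_query")
}

#' Define an adverse event of interest
#'
#' @param terms MedDRA preferred-term strings (matched case-insensitively,
#'   as opaque labels — no MedDRA hierarchy expansion).
#' @return an `event_query` object.
#' @export
event_query <- function(terms) {
  terms <- squish(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("event_query needs at least one preferred term")
  structure(list(terms = unique(toupper(terms))), class = "event_query")
}

#' Which cases carry the drug?
#'
#' A case matches when at least one of its drug rows matches a query name
#' under the query's match mode *and* has a qualifying role code.
#'
#' @param cases a [deduplicate_cases()] result.
#' @param q a [drug_query()].
#' @return logical vector aligned with `cases$demo` rows.
#' @export
case_has_drug <- function(cases, q) {
  stopifnot(inherits(cases, "faers_cases"), inherits(q, "drug_query"))
  drug <- cases$drug[role_cod %in% q$roles]
  norm <- normalize_drugname(drug$drugname)
  hit <- if (q$match == "exact") {
    norm %in% q$names
  } else {
    Reduce(`|`, lapply(q$names, function(nm) {
      !is.na(norm) & grepl(nm, norm, fixed = TRUE)
    }), init = rep(FALSE, length(norm)))
  }
  cases$demo$primaryid %in% drug$primaryid[hit]
}

#' Which cases report the event?
#'
#' Exact case-insensitive preferred-term equality against the query's terms.
#'
#' @param cases a [deduplicate_cases()] result.
#' @param q an [event_query()].
#' @return logical vector aligned with `cases$demo` rows.
#' @export
case_has_event <- function(cases, q) {
  stopifnot(inherits(cases, "faers_cases"), inherits(q, "event_query"))
  hit <- toupper(squish(cases$reac$pt)) %in% q$terms
  cases$demo$primaryid %in% cases$reac$primaryid[hit]
}
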