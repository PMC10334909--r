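#' Solve background 2x2 cells for a target PRR
#'
#' Given the exposed-case cells `a` (drug and event) and `b` (drug, no
#' event), finds background cells `c`, `d` by grid search so that the
#' resulting table's PRR lands within `prr_tol` of `prr_target`, preferring
#' the grid point whose full statistic set (Yates chi-square, ROR, IC025)
#' best matches the optional `secondary` targets.  Used by
#' [make_avapritinib_fixture()] to reconstruct a report universe consistent
#' with all four published headline statistics at once.
#'
#' @param a,b exposed cells.
#' @param prr_target target PRR.
#' @param prr_tol admissible deviation (default 0.05).
#' @param secondary named list of further targets among `chi2`, `ror`,
#'   `ic025` used to rank admissible grid points.
#' @param c_grid candidate values for the `c` cell.
#' @return list with `c`, `d` and the achieved statistics.
#' @export
solve_background <- function(a = 13, b = 2000, prr_target = 11,
                             prr_tol = 0.05,
                             secondary = list(chi2 = 107, ror = 11, ic025 = 2.1),
                             c_grid = seq(200L, 4000L, by = 5L)) {
  r <- (a / (a + b)) / prr_target        # background event rate hitting PRR
  cand <- data.table::data.table(c = as.numeric(c_grid))
  cand[, "d" := round(c / r) - c]
  cand <- cand[d > 0]
  s <- dispro_core(a, b, cand$c, cand$d, yates = TRUE)
  ok <- abs(s$prr - prr_target) <= prr_tol
  if (!any(ok)) stop("no admissible background on the grid; widen c_grid")
  score <- rep(Inf, nrow(s))
  score[ok] <- 0
  for (nm in names(secondary)) {
    score[ok] <- score[ok] +
      abs(s[[nm]][ok] - secondary[[nm]]) / abs(secondary[[nm]])
  }
  best <- which.min(score)
  list(c = as.integer(cand$c[best]), d = as.integer(cand$d[best]),
       prr = s$prr[best], chi2 = s$chi2[best], ror = s$ror[best],
       ic025 = s$ic025[best])
}

# the 13-case Avapritinib/photosensitivity series: 11 M / 2 F; known ages
# 31,45,50,52,60,62,65,66,68,70,71,80 (mean 60, range 31-80; bins
# 3/2/5/2 with one unknown); indications 9 GIST / 4 systemic mastocytosis;
# 5 serious; all US; one case with 8 co-medications, the rest
# avapritinib-only; receipt dates spanning May 2020 to November 2021.
series_cases <- function() {
  ages <- c(31, 45, 50, 52, 60, 62, 65, 66, 68, 70, 71, 80, NA)
  sex <- rep("M", 13); sex[c(2, 8)] <- "F"
  indication <- c(rep("Gastrointestinal stromal tumour", 9),
                  rep("Systemic mastocytosis", 4))
  serious_code <- c("HO", NA, "DE", NA, "HO", NA, NA, "LT", NA, NA, NA, "OT", NA)
  dates <- as.Date(c("2020-05-15", "2020-07-02", "2020-09-20", "2020-11-11",
                     "2021-01-08", "2021-02-14", "2021-04-03", "2021-05-22",
                     "2021-06-30", "2021-08-09", "2021-09-17", "2021-10-05",
                     "2021-11-19"))
  caseid <- sprintf("%08d", 20000000L + seq_len(13L))
  primaryid <- paste0(caseid, "1")
  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    fda_dt = dates, event_dt = dates - 21L, age = ages,
    age_cod = ifelse(is.na(ages), NA_character_, "YR"),
    sex = sex, occr_country = "US")
  drug <- data.table::data.table(
    primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
    drugname = "AVAPRITINIB", indi_pt = indication)
  comeds <- c("INSULIN GLARGINE", "INSULIN ASPART", "ONDANSETRON",
              "DIPHENHYDRAMINE", "LORATADINE", "LOPERAMIDE", "BISACODYL",
              "TRAMADOL")
  drug <- rbind(drug, data.table::data.table(
    primaryid = primaryid[13], drug_seq = seq_along(comeds) + 1L,
    role_cod = "C", drugname = comeds, indi_pt = NA_character_))
  coreported <- c("Oedema peripheral", "Lacrimation increased", "Fatigue",
                  "Rash", "Abdominal discomfort", "Diarrhoea")
  reac <- data.table::data.table(
    primaryid = primaryid, pt = "Photosensitivity reaction")
  reac <- rbind(reac, data.table::data.table(
    primaryid = primaryid[seq_along(coreported)], pt = coreported))
  outc <- data.table::data.table(
    primaryid = primaryid[!is.na(serious_code)],
    outc_cod = serious_code[!is.na(serious_code)])
  list(demo = demo, drug = drug, reac = reac, outc = outc)
}

# deterministic background block of nb cases: one drug row and one reaction
# row each, fields cycled (no RNG, so the fixture is byte-stable)
background_cases <- function(nb, offset, drugs, reactions, indications = NULL,
                             roles = c("PS", "PS", "PS", "C"),
                             window = as.Date(c("2020-01-01", "2021-12-31"))) {
  if (nb == 0L) {
    return(list(demo = data.table::data.table(), drug = data.table::data.table(),
                reac = data.table::data.table(), outc = data.table::data.table()))
  }
  cyc <- function(v, n) rep_len(v, n)
  caseid <- as.character(offset + seq_len(nb))
  primaryid <- paste0(caseid, "1")
  days <- as.integer(window[2] - window[1])
  dates <- window[1] + (seq_len(nb) * 37L) %% (days + 1L)
  ages <- cyc(20:85, nb)
  miss <- seq_len(nb) %% 17L == 0L
  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    fda_dt = dates, event_dt = dates - 14L,
    age = ifelse(miss, NA_real_, as.numeric(ages)),
    age_cod = ifelse(miss, NA_character_, "YR"),
    sex = cyc(c("M", "F", "M", "F", "UNK"), nb),
    occr_country = cyc(c("US", "US", "US", "GB", "JP"), nb))
  drug <- data.table::data.table(
    primaryid = primaryid, drug_seq = 1L,
    role_cod = cyc(roles, nb),
    drugname = cyc(drugs, nb),
    indi_pt = if (is.null(indications)) NA_character_ else cyc(indications, nb))
  reac <- data.table::data.table(primaryid = primaryid, pt = cyc(reactions, nb))
  serious <- seq_len(nb) %% 4L == 0L
  outc <- data.table::data.table(
    primaryid = primaryid[serious],
    outc_cod = cyc(c("HO", "OT", "DE", "LT", "DS"), sum(serious)))
  list(demo = demo, drug = drug, reac = reac, outc = outc)
}

#' Reconstruct the Avapritinib-photosensitivity report universe
#'
#' Builds a synthetic FAERS dataset whose deduplicated
#' Avapritinib-photosensitivity case series has exactly the published
#' marginals: 13 cases, 11 male / 2 female, mean age 60 (range 31-80) with
#' age bins 3/2/5/2/1 over 31-50/51-60/61-70/71-80/Unknown, indications
#' 9 gastrointestinal stromal tumour / 4 systemic mastocytosis, 5 serious,
#' all reported from the US, Avapritinib the suspect drug in all 13 and the
#' only drug in 12.  The background cells (`b` Avapritinib-only cases, `c`
#' photosensitivity-only cases, `d` neither) are not published; by default a
#' small background is used, sized for demographic tests.  With
#' `prr_match = TRUE` the background is solved by [solve_background()] so
#' that the full universe also reproduces PRR = 11.0 (and, as a
#' consequence of the published statistics being mutually consistent,
#' chi-square ~107, ROR ~11 and IC025 ~2.1); this universe has about two
#' million cases.
#'
#' Two duplicate report versions (one series case, one background case,
#' differing only in receipt date) are injected so the fixture also
#' exercises deduplication.  The fixture is fully deterministic.
#'
#' @param prr_match solve the background so PRR = 11.0 +/- 0.05.
#' @param background optional `list(b=, c=, d=)` overriding the default
#'   background cells.
#' @param dir if non-`NULL`, write the dataset there as FAERS quarterly
#'   tables.
#' @return a [faers_dataset()]; attribute `"ground_truth"` holds the
#'   intended 2x2 cells, the expected Table-1 counts, and the injected
#'   duplicate `primaryid`s.
#' @export
make_avapritinib_fixture <- function(prr_match = FALSE, background = NULL,
                                     dir = NULL) {
  if (is.null(background)) {
    background <- if (prr_match) {
      sb <- solve_background(a = 13, b = 2000, prr_target = 11)
      list(b = 2000L, c = sb$c, d = sb$d)
    } else {
      list(b = 50L, c = 40L, d = 500L)
    }
  }
  series <- series_cases()
  coreported <- c("Oedema peripheral", "Lacrimation increased", "Fatigue",
                  "Rash", "Abdominal discomfort", "Diarrhoea", "Nausea",
                  "Headache")
  other_drugs <- c("IMATINIB", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
                   "OMEPRAZOLE", "AMOXICILLIN", "ASPIRIN")
  bg_b <- background_cases(background$b, 30000000L, "AVAPRITINIB",
                           coreported, roles = "PS",
                           indications = c("Gastrointestinal stromal tumour",
                                           "Systemic mastocytosis"))
  bg_c <- background_cases(background$c, 40000000L, other_drugs,
                           "Photosensitivity reaction")
  bg_d <- background_cases(background$d, 50000000L, other_drugs, coreported)

  demo <- data.table::rbindlist(list(series$demo, bg_b$demo, bg_c$demo, bg_d$demo))
  drug <- data.table::rbindlist(list(series$drug, bg_b$drug, bg_c$drug, bg_d$drug))
  reac <- data.table::rbindlist(list(series$reac, bg_b$reac, bg_c$reac, bg_d$reac))
  outc <- data.table::rbindlist(list(series$outc, bg_b$outc, bg_c$outc, bg_d$outc))

  # follow-up versions differing only in receipt date: one series case,
  # one background case
  dup_src <- demo[primaryid %in% c(series$demo$primaryid[5],
                                   bg_d$demo$primaryid[1])]
  dup <- data.table::copy(dup_src)
  dup[, "caseversion" := 2L]
  dup[, "primaryid" := paste0(caseid, "2")]
  dup[, "fda_dt" := fda_dt + 30L]
  redup <- function(tab) {
    ch <- tab[tab$primaryid %in% dup_src$primaryid]
    if (nrow(ch)) ch[, "primaryid" := paste0(substr(primaryid, 1,
                                                    nchar(primaryid) - 1L), "2")]
    ch
  }
  demo <- rbind(demo, dup)
  drug <- rbind(drug, redup(data.table::copy(drug)))
  reac <- rbind(reac, redup(data.table::copy(reac)))
  outc <- rbind(outc, redup(data.table::copy(outc)))

  ds <- faers_dataset(demo, drug, reac, outc)
  attr(ds, "ground_truth") <- list(
    cells = list(a = 13L, b = as.integer(background$b),
                 c = as.integer(background$c), d = as.integer(background$d)),
    duplicate_primaryids = dup$primaryid,
    table1 = list(n = 13L, male = 11L, female = 2L,
                  age_bins = c(`31-50` = 3L, `51-60` = 2L, `61-70` = 5L,
                               `71-80` = 2L, Unknown = 1L),
                  gist = 9L, mastocytosis = 4L, serious = 5L,
                  age_mean = 60, age_range = c(31, 80)))
  if (!is.null(dir)) write_faers_dataset(ds, dir)
  ds
}

#' Query preset for the Avapritinib-photosensitivity pair
#'
#' The drug and event queries of the published analysis: generic and trade
#' names of avapritinib, suspect roles only, and the MedDRA preferred term
#' "Photosensitivity reaction".
#'
#' @return list with elements `drug` ([drug_query()]) and `event`
#'   ([event_query()]).
#' @export
avapritinib_queries <- function() {
  list(drug = drug_query(c("AVAPRITINIB", "AYVAKIT"), roles = c("PS", "SS")),
       event = event_query("Photosensitivity reaction"))
}
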