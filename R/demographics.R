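#' Convert a FAERS age value/unit pair to years
#'
#' FAERS reports carry age with a unit code: `YR` years, `DEC` decades,
#' `MON` months, `WK` weeks, `DY` days, `HR` hours.  Conversion uses the
#' mean Gregorian year (365.25 days, 52.1775 weeks, 8766 hours).
#'
#' @param value nonnegative numeric vector.
#' @param unit character vector of unit codes (recycled with `value`).
#' @return age in years; `NA` (logged via warning count) for unknown units.
#' @export
#' @examples
#' age_in_years(c(60, 6, 730.5), c("YR", "DEC", "DY"))
age_in_years <- function(value, unit) {
  factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor[toupper(as.character(unit))]
  unknown <- !is.na(unit) & is.na(f) & !is.na(value)
  if (any(unknown)) {
    warning(sprintf("%d age value(s) with unrecognized unit treated as missing",
                    sum(unknown)))
  }
  unname(value * f)
}

default_age_bins <- function() {
  list(c(31, 50), c(51, 60), c(61, 70), c(71, 80))
}

# assign integer ages (completed years) to closed bins; NA -> "Unknown";
# ages below/above the configured span get automatically added open bins
bin_ages <- function(years, bins = default_age_bins()) {
  lows <- vapply(bins, `[[`, numeric(1), 1L)
  his <- vapply(bins, `[[`, numeric(1), 2L)
  labels <- sprintf("%g-%g", lows, his)
  age <- floor(years)
  out <- rep(NA_character_, length(age))
  for (i in seq_along(bins)) {
    out[!is.na(age) & age >= lows[i] & age <= his[i]] <- labels[i]
  }
  below <- sprintf("<%g", min(lows)); above <- sprintf(">%g", max(his))
  out[!is.na(age) & is.na(out) & age < min(lows)] <- below
  out[!is.na(age) & is.na(out) & age > max(his)] <- above
  out[is.na(age)] <- "Unknown"
  lev <- c(if (any(out == below)) below, labels,
           if (any(out == above)) above, "Unknown")
  factor(out, levels = lev)
}

count_pct <- function(f, n) {
  cnt <- table(f)
  data.table::data.table(level = names(cnt), count = as.integer(cnt),
                         percent = pct_of(as.integer(cnt), n))
}

#' Table-1 style demographic summary of a drug-event case series
#'
#' Restricts the case universe to cases matching both queries and tabulates
#' sex, age bins (closed on both ends, e.g. "31-50" includes 31 and 50;
#' missing age goes to "Unknown"; ages outside the configured span get
#' automatically added open bins so no case is lost), the indication
#' recorded for the queried drug, and seriousness (any outcome code among
#' DE/LT/HO/DS/CA/RI/OT).  Percentages are integers rounded half away from
#' zero, so a column may not sum to exactly 100.
#'
#' @param cases a [deduplicate_cases()] result.
#' @param drug a [drug_query()].
#' @param event an [event_query()].
#' @param age_bins list of `c(low, high)` closed integer bins; default
#'   `list(c(31,50), c(51,60), c(61,70), c(71,80))`.
#' @return an object of class `faers_table1`: list with `n`, `sex`,
#'   `age`, `indication`, `seriousness`, `country` (`data.table`s of
#'   level/count/percent), `age_mean_years`, `age_range_years`.
#' @export
summarize_demographics <- function(cases, drug, event,
                                   age_bins = default_age_bins()) {
  stopifnot(inherits(cases, "faers_cases"))
  sel <- case_has_drug(cases, drug) & case_has_event(cases, event)
  n <- sum(sel)
  if (n == 0L) stop("no cases match both the drug and the event query")
  demo <- cases$demo[sel]

  sex <- factor(ifelse(is.na(demo$sex), "UNK", demo$sex),
                levels = c("M", "F", "UNK"))
  sex_dt <- count_pct(sex, n)
  sex_dt <- sex_dt[sex_dt$count > 0 | sex_dt$level != "UNK"]

  years <- suppressWarnings(age_in_years(demo$age, demo$age_cod))
  age_dt <- count_pct(bin_ages(years, age_bins), n)

  # indication of the queried drug on each case (lowest matching drug_seq)
  drows <- cases$drug[primaryid %in% demo$primaryid & role_cod %in% drug$roles]
  dnorm <- normalize_drugname(drows$drugname)
  m <- if (drug$match == "exact") dnorm %in% drug$names else
    Reduce(`|`, lapply(drug$names, function(nm) !is.na(dnorm) &
                         grepl(nm, dnorm, fixed = TRUE)),
           init = rep(FALSE, length(dnorm)))
  drows <- drows[m][order(primaryid, drug_seq)]
  first <- drows[!duplicated(primaryid)]
  ind <- first$indi_pt[match(demo$primaryid, first$primaryid)]
  ind[is.na(ind)] <- "Unknown"
  ind_dt <- count_pct(factor(ind), n)
  data.table::setorder(ind_dt, -count, level)

  ser <- factor(ifelse(demo$serious, "Serious", "Non-serious"),
                levels = c("Serious", "Non-serious"))
  ser_dt <- count_pct(ser, n)

  ctry <- demo$occr_country
  ctry[is.na(ctry)] <- "Unknown"
  ctry_dt <- count_pct(factor(ctry), n)
  data.table::setorder(ctry_dt, -count, level)

  known <- years[!is.na(years)]
  structure(list(
    n = n,
    sex = sex_dt, age = age_dt, indication = ind_dt, seriousness = ser_dt,
    country = ctry_dt,
    age_mean_years = if (length(known)) mean(known) else NA_real_,
    age_range_years = if (length(known)) range(known) else c(NA_real_, NA_real_)
  ), class = "faers_table1")
}

#' @export
print.faers_table1 <- function(x, ...) {
  cat(sprintf("Case series demographic summary (N=%d), n (%%)\n", x$n))
  block <- function(title, dt, label_map = identity) {
    cat(title, "\n")
    for (i in seq_len(nrow(dt))) {
      cat(sprintf("  %-52s %d (%d)\n", label_map(dt$level[i]),
                  dt$count[i], dt$percent[i]))
    }
  }
  block("Sex", x$sex, function(l) c(M = "Male", F = "Female", UNK = "Unknown")[l])
  block("Age (years)", x$age)
  if (!is.na(x$age_mean_years)) {
    cat(sprintf("  mean %.0f, range %.0f-%.0f\n", x$age_mean_years,
                x$age_range_years[1], x$age_range_years[2]))
  }
  block("Indication", x$indication)
  block("Seriousness", x$seriousness,
        function(l) c(Serious = paste("Resulted in death, life-threatening,",
                                      "hospitalization, disability,",
                                      "congenital anomaly, or other serious"),
                      `Non-serious` = "Did not result in above")[l])
  block("Reporting country", x$country)
  invisible(x)
}

#' Flatten a demographic summary to one long data.table
#'
#' @param x a `faers_table1`.
#' @param ... unused.
#' @return `data.table` with columns `section`, `level`, `count`, `percent`.
#' @method as.data.table faers_table1
#' @export
as.data.table.faers_table1 <- function(x, ...) {
  secs <- c("sex", "age", "indication", "seriousness", "country")
  data.table::rbindlist(
    lapply(secs, function(s) data.table::data.table(section = s, x[[s]])))
}
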