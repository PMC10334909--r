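#' Construct a drug-event 2x2 contingency table
#'
#' Cell layout over a case universe: `a` = cases with drug and event, `b` =
#' drug without event, `c` = event without drug, `d` = neither;
#' `n = a + b + c + d`.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param drug,event optional labels carried through to results.
#' @return an object of class `faers_2x2`.
#' @export
contingency_table <- function(a, b, c, d, drug = NULL, event = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells a, b, c, d must be nonnegative integers")
  }
  n <- sum(cells)
  if (n < 1) stop("contingency table must contain at least one case (n >= 1)")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(n),
                 drug = drug, event = event),
            class = "faers_2x2")
}

#' @export
print.faers_2x2 <- function(x, ...) {
  lab <- function(l, alt) if (is.null(l)) alt else l
  cat(sprintf("<faers_2x2> %s x %s\n", lab(x$drug, "drug"), lab(x$event, "event")))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  cat("n =", format(x$n, big.mark = ","), "\n")
  invisible(x)
}

#' Tabulate a drug-event pair over deduplicated cases
#'
#' @param cases a [deduplicate_cases()] result.
#' @param drug a [drug_query()].
#' @param event an [event_query()].
#' @return a [contingency_table()] with `n` equal to the number of cases.
#' @export
build_contingency <- function(cases, drug, event) {
  stopifnot(inherits(cases, "faers_cases"))
  if (nrow(cases$demo) == 0L) stop("empty case universe: n >= 1 required")
  has_d <- case_has_drug(cases, drug)
  has_e <- case_has_event(cases, event)
  contingency_table(sum(has_d & has_e), sum(has_d & !has_e),
                    sum(!has_d & has_e), sum(!has_d & !has_e),
                    drug = paste(drug$names, collapse = "/"),
                    event = paste(event$terms, collapse = "/"))
}

# Vectorized statistical core shared by the scalar API and screen_pairs().
# All inputs are numeric vectors of cell counts; returns a data.table.
dispro_core <- function(a, b, c, d, yates = TRUE, z = 1.96) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  n <- a + b + c + d
  drug_tot <- a + b; event_tot <- a + c
  no_drug_tot <- c + d; no_event_tot <- b + d

  prr_defined <- drug_tot > 0 & c > 0
  prr <- ifelse(drug_tot > 0, (a / drug_tot) / (c / no_drug_tot), NaN)

  chi2_defined <- drug_tot > 0 & no_drug_tot > 0 & event_tot > 0 & no_event_tot > 0
  dev <- a * d - b * c
  num <- if (yates) pmax(abs(dev) - n / 2, 0)^2 else dev^2
  chi2 <- ifelse(chi2_defined,
                 n * num / (drug_tot * no_drug_tot * event_tot * no_event_tot),
                 NaN)

  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  h <- ifelse(corrected, 0.5, 0)
  a2 <- a + h; b2 <- b + h; c2 <- c + h; d2 <- d + h
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ror_lo <- exp(log(ror) - z * se)
  ror_hi <- exp(log(ror) + z * se)

  expected <- drug_tot * event_tot / n
  ic <- log2((a + 0.5) / (expected + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)

  data.table::data.table(a = a, b = b, c = c, d = d, n = n,
                         expected = expected,
                         prr = prr, prr_defined = prr_defined,
                         chi2 = chi2, chi2_defined = chi2_defined,
                         yates = yates,
                         ror = ror, ror_lower = ror_lo, ror_upper = ror_hi,
                         ror_corrected = corrected,
                         ic = ic, ic025 = ic025)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the proportion of the drug's cases
#' reporting the event, relative to the same proportion among all other
#' cases.  When `c = 0` or `a + b = 0` the ratio is undefined; a flagged
#' non-finite value is returned (rather than an error) so that screening
#' over many pairs continues.
#'
#' @param t a [contingency_table()].
#' @return numeric; attribute `"defined"` is `FALSE` when flagged.
#' @export
prr <- function(t) {
  stopifnot(inherits(t, "faers_2x2"))
  s <- dispro_core(t$a, t$b, t$c, t$d)
  structure(s$prr, defined = s$prr_defined)
}

#' Pearson chi-square statistic of a 2x2 table (1 df)
#'
#' Without continuity correction: `n(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`.
#' With the Yates correction (the default, as in the classical PRR signal
#' criterion): `n(|ad - bc| - n/2)^2` over the same denominator, floored at
#' zero when `|ad - bc| < n/2`.  A zero marginal makes the statistic
#' undefined; a flagged `NaN` is returned.
#'
#' @param t a [contingency_table()].
#' @param yates apply the continuity correction? Default `TRUE`.
#' @return numeric; attributes `"defined"` and `"yates"`.
#' @export
chi_square <- function(t, yates = TRUE) {
  stopifnot(inherits(t, "faers_2x2"))
  s <- dispro_core(t$a, t$b, t$c, t$d, yates = yates)
  structure(s$chi2, defined = s$chi2_defined, yates = yates)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/(bc)`; the Woolf interval
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero the Haldane-Anscombe correction (0.5 added to every cell) is applied
#' and the result flagged `corrected`.
#'
#' @param t a [contingency_table()].
#' @return list with `ror`, `lower`, `upper`, `corrected`.
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "faers_2x2"))
  s <- dispro_core(t$a, t$b, t$c, t$d)
  list(ror = s$ror, lower = s$ror_lower, upper = s$ror_upper,
       corrected = s$ror_corrected)
}

#' Shrinkage information component and IC025 credibility bound
#'
#' The expected count under independence is `E = (a+b)(a+c)/n`.  The
#' shrunken observed-to-expected log ratio is
#' `IC = log2((a + 0.5)/(E + 0.5))`, and the lower end of its 95%
#' credibility interval is approximated in closed form as
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`.
#' The shrinkage makes both quantities defined for every table.
#'
#' @param t a [contingency_table()].
#' @return list with `ic`, `ic025`, `expected`.
#' @seealso [information_component_mc()] for the Monte-Carlo check of the
#'   closed-form credibility bound.
#' @export
information_component <- function(t) {
  stopifnot(inherits(t, "faers_2x2"))
  s <- dispro_core(t$a, t$b, t$c, t$d)
  list(ic = s$ic, ic025 = s$ic025, expected = s$expected)
}

#' Monte-Carlo credibility bound for the information component
#'
#' Simulation-based counterpart of the closed-form `IC025` in
#' [information_component()], used to defend the approximation: the observed
#' count is modelled as Poisson with a Gamma(0.5, rate 0.5/ (scaled)) style
#' shrinkage prior, giving the posterior `lambda ~ Gamma(a + 0.5, rate
#' E + 0.5)` for the observed-to-expected ratio; the bound is the 2.5th
#' percentile of `log2(lambda)` over random draws.
#'
#' @param t a [contingency_table()].
#' @param n_draws number of posterior draws.
#' @param quantile_p percentile (default 0.025).
#' @return the Monte-Carlo percentile of the IC posterior (log2 scale).
#' @export
information_component_mc <- function(t, n_draws = 1e6, quantile_p = 0.025) {
  stopifnot(inherits(t, "faers_2x2"))
  e <- (t$a + t$b) * (t$a + t$c) / t$n
  draws <- stats::rgamma(n_draws, shape = t$a + 0.5, rate = e + 0.5)
  unname(stats::quantile(log2(draws), quantile_p))
}

#' Full disproportionality analysis of one 2x2 table
#'
#' Computes PRR, chi-square, ROR with 95% CI, expected count, IC and IC025,
#' and attaches the three signal-criteria verdicts from
#' [evaluate_signal()].
#'
#' @param t a [contingency_table()].
#' @param yates chi-square continuity correction, default `TRUE`.
#' @param min_events minimum case count in the classical criterion
#'   (default 3).
#' @return an object of class `faers_signal`.
#' @export
disproportionality <- function(t, yates = TRUE, min_events = 3) {
  stopifnot(inherits(t, "faers_2x2"))
  s <- dispro_core(t$a, t$b, t$c, t$d, yates = yates)
  res <- structure(c(as.list(s), list(n_events = s$a, drug = t$drug,
                                      event = t$event)),
                   class = "faers_signal")
  res$criteria <- evaluate_signal(res, min_events = min_events)
  res
}

#' Signal-criteria verdicts
#'
#' Three criteria are evaluated on a computed result, each with inclusive
#' thresholds where the rule states them:
#' * `evans`: `PRR >= 2` and `chi2 >= 4` and at least `min_events` cases
#'   (the classical PRR criterion);
#' * `ror_rule`: `ROR > 1`;
#' * `ic_rule`: `IC025 > 0`.
#'
#' Each verdict is reported separately, together with `all_three`, their
#' conjunction.  A statistic flagged undefined makes its criterion `FALSE`,
#' with the reason recorded in `notes`.
#'
#' @param r a `faers_signal` (or any list carrying `prr`, `chi2`,
#'   `prr_defined`, `chi2_defined`, `ror`, `ic025`, `n_events`).
#' @param min_events minimum case count for the classical rule (default 3).
#' @return list with logicals `evans`, `ror_rule`, `ic_rule`, `all_three`
#'   and a character vector `notes`.
#' @export
evaluate_signal <- function(r, min_events = 3) {
  notes <- character()
  prr_ok <- isTRUE(r$prr_defined %||% TRUE) && is.finite(r$prr)
  chi_ok <- isTRUE(r$chi2_defined %||% TRUE) && is.finite(r$chi2)
  if (!prr_ok) notes <- c(notes, "PRR undefined (zero denominator); evans criterion set FALSE")
  if (!chi_ok) notes <- c(notes, "chi-square undefined (zero marginal); evans criterion set FALSE")
  evans <- prr_ok && chi_ok &&
    r$prr >= 2 && r$chi2 >= 4 && r$n_events >= min_events
  ror_rule <- is.finite(r$ror) && r$ror > 1
  if (!is.finite(r$ror)) notes <- c(notes, "ROR undefined; ror_rule set FALSE")
  ic_rule <- is.finite(r$ic025) && r$ic025 > 0
  list(evans = evans, ror_rule = ror_rule, ic_rule = ic_rule,
       all_three = evans && ror_rule && ic_rule, notes = notes)
}

#' @export
print.faers_signal <- function(x, ...) {
  lab <- function(l, alt) if (is.null(l)) alt else l
  cat(sprintf("<faers_signal> %s x %s\n", lab(x$drug, "drug"), lab(x$event, "event")))
  cat(sprintf("  cases a = %d of n = %s (expected %.2f)\n",
              as.integer(x$a), format(x$n, big.mark = ","), x$expected))
  cat(sprintf("  PRR   = %.2f%s\n", x$prr,
              if (!x$prr_defined) " [undefined]" else ""))
  cat(sprintf("  chi2  = %.1f (%s)%s\n", x$chi2,
              if (x$yates) "Yates-corrected" else "uncorrected",
              if (!x$chi2_defined) " [undefined]" else ""))
  cat(sprintf("  ROR   = %.2f (95%% CI %.2f-%.2f)%s\n",
              x$ror, x$ror_lower, x$ror_upper,
              if (x$ror_corrected) " [Haldane-Anscombe corrected]" else ""))
  cat(sprintf("  IC    = %.2f, IC025 = %.2f\n", x$ic, x$ic025))
  cr <- x$criteria
  cat(sprintf("  criteria: PRR>=2 & chi2>=4 & a>=3: %s | ROR>1: %s | IC025>0: %s | all three: %s\n",
              cr$evans, cr$ror_rule, cr$ic_rule, cr$all_three))
  for (nt in cr$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Coerce a screening result or signal to a flat data.table
#'
#' @param x a `faers_signal`.
#' @param ... unused.
#' @return one-row `data.table` with all statistics, flags and verdicts.
#' @method as.data.table faers_signal
#' @export
as.data.table.faers_signal <- function(x, ...) {
  data.table::data.table(
    drug = x$drug %||% NA_character_, event = x$event %||% NA_character_,
    a = x$a, b = x$b, c = x$c, d = x$d, n = x$n, expected = x$expected,
    prr = x$prr, prr_defined = x$prr_defined,
    chi2 = x$chi2, chi2_defined = x$chi2_defined, yates = x$yates,
    ror = x$ror, ror_lower = x$ror_lower, ror_upper = x$ror_upper,
    ror_corrected = x$ror_corrected, ic = x$ic, ic025 = x$ic025,
    evans = x$criteria$evans, ror_rule = x$criteria$ror_rule,
    ic_rule = x$criteria$ic_rule, all_three = x$criteria$all_three)
}

#' Screen every drug-event pair in a case universe
#'
#' Builds the 2x2 table for each (normalized drug name, preferred term)
#' pair with at least `min_a` co-reporting cases and computes the full
#' statistic set, ranked by descending IC025 (the most shrinkage-robust key
#' for small counts), ties broken by (drug, event) lexicographic order.
#' Pair counting is sparse-matrix based and scales to the full database.
#'
#' @param cases a [deduplicate_cases()] result.
#' @param min_a minimum `a` cell for a pair to be reported (default 3, the
#'   classical minimum case count).
#' @param roles drug role codes that count as exposure (default suspects
#'   `c("PS","SS")`).
#' @param yates chi-square continuity correction, default `TRUE`.
#' @return a `data.table`, one row per pair, all statistics and verdicts.
#' @export
screen_pairs <- function(cases, min_a = 3, roles = c("PS", "SS"), yates = TRUE) {
  stopifnot(inherits(cases, "faers_cases"))
  ids <- cases$demo$primaryid
  n <- length(ids)
  if (n == 0L) stop("empty case universe")

  drug <- cases$drug[role_cod %in% roles]
  dnorm <- normalize_drugname(drug$drugname)
  keep <- !is.na(dnorm)
  d_case <- match(drug$primaryid[keep], ids)
  d_name <- factor(dnorm[keep])

  reac <- cases$reac
  enorm <- toupper(squish(reac$pt))
  ekeep <- !is.na(enorm) & nzchar(enorm)
  e_case <- match(reac$primaryid[ekeep], ids)
  e_name <- factor(enorm[ekeep])

  if (length(d_case) == 0L || length(e_case) == 0L) {
    return(data.table::data.table())
  }
  dm <- Matrix::sparseMatrix(i = d_case, j = as.integer(d_name), x = 1,
                             dims = c(n, nlevels(d_name)))
  em <- Matrix::sparseMatrix(i = e_case, j = as.integer(e_name), x = 1,
                             dims = c(n, nlevels(e_name)))
  dm@x[] <- 1; em@x[] <- 1  # membership, not row multiplicity

  a_mat <- as.matrix(Matrix::crossprod(dm, em))
  drug_tot <- Matrix::colSums(dm)
  event_tot <- Matrix::colSums(em)

  hit <- which(a_mat >= min_a, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(data.table::data.table())
  a <- a_mat[hit]
  b <- drug_tot[hit[, 1]] - a
  cc <- event_tot[hit[, 2]] - a
  dd <- n - a - b - cc
  res <- dispro_core(a, b, cc, dd, yates = yates)
  res[, "drug" := levels(d_name)[hit[, 1]]]
  res[, "event" := levels(e_name)[hit[, 2]]]
  res[, "evans" := prr_defined & chi2_defined & prr >= 2 & chi2 >= 4 & a >= 3]
  res[, "ror_rule" := is.finite(ror) & ror > 1]
  res[, "ic_rule" := ic025 > 0]
  res[, "all_three" := evans & ror_rule & ic_rule]
  data.table::setorder(res, -ic025, drug, event)
  data.table::setcolorder(res, c("drug", "event"))
  res[]
}
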