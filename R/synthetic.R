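#' Configuration for the synthetic FAERS generator
#'
#' Describes a spontaneous-report universe with known ground truth.  Each
#' case independently receives each drug with its marginal reporting
#' probability; the probability of each event is its marginal tilted by the
#' largest association ratio `rho` among the drugs present on the case,
#' `P(event | drugs) = min(1, p_e * max(rho))`, so `rho` plays the role of
#' the relative reporting rate that PRR/ROR estimate (`rho = 1` is
#' independence).  A fraction of cases is re-emitted as a higher
#' `caseversion` with a later receipt date and jittered age, so
#' deduplication correctness is observable.
#'
#' @param n_cases number of distinct cases (>= 1).
#' @param drugs named numeric vector: marginal reporting probability per
#'   drug name.
#' @param events named numeric vector: marginal probability per MedDRA
#'   preferred term.
#' @param associations `data.frame`/`data.table` with columns `drug`,
#'   `event`, `rho` (pairs not listed default to `rho = 1`).
#' @param duplicate_version_rate fraction of cases re-emitted as a
#'   follow-up version.
#' @param suspect_role_probability probability that a drug row is coded
#'   suspect (PS), else concomitant (C).
#' @param sex_probabilities named probabilities over `M`, `F`, `UNK`.
#' @param age_mixture `data.frame` with columns `low`, `high`, `weight`:
#'   ages are drawn uniformly within a bin chosen by weight.
#' @param age_missing_rate share of cases with missing age.
#' @param serious_probability probability a case carries a serious outcome
#'   code.
#' @param indication_map named character: indication PT recorded for each
#'   drug (drugs not listed get no indication row).
#' @param window `c(start, end)` dates over which receipt dates are drawn.
#' @param seed master seed; all randomness flows from it, so equal seeds
#'   give byte-identical files.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 10000,
                             drugs = stats::setNames(rep(0.08, 5), paste0("DRUG_", LETTERS[1:5])),
                             events = stats::setNames(rep(0.08, 5), paste0("Event ", LETTERS[1:5])),
                             associations = NULL,
                             duplicate_version_rate = 0.1,
                             suspect_role_probability = 0.9,
                             sex_probabilities = c(M = 0.45, F = 0.45, UNK = 0.10),
                             age_mixture = data.frame(
                               low = c(18, 31, 51, 61, 71),
                               high = c(30, 50, 60, 70, 85),
                               weight = c(0.1, 0.25, 0.2, 0.3, 0.15)),
                             age_missing_rate = 0.08,
                             serious_probability = 0.3,
                             indication_map = NULL,
                             window = c("2020-01-01", "2021-12-31"),
                             seed = 1L) {
  stopifnot(n_cases >= 1,
            all(drugs >= 0 & drugs <= 1), all(events >= 0 & events <= 1),
            duplicate_version_rate >= 0, duplicate_version_rate <= 1,
            suspect_role_probability >= 0, suspect_role_probability <= 1)
  if (is.null(associations)) {
    associations <- data.table::data.table(drug = character(),
                                           event = character(),
                                           rho = numeric())
  } else {
    associations <- data.table::as.data.table(associations)
    stopifnot(all(c("drug", "event", "rho") %in% names(associations)),
              all(associations$rho >= 0))
  }
  structure(list(n_cases = as.integer(n_cases), drugs = drugs, events = events,
                 associations = associations,
                 duplicate_version_rate = duplicate_version_rate,
                 suspect_role_probability = suspect_role_probability,
                 sex_probabilities = sex_probabilities,
                 age_mixture = age_mixture,
                 age_missing_rate = age_missing_rate,
                 serious_probability = serious_probability,
                 indication_map = indication_map,
                 window = as.Date(window), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic FAERS universe with known ground truth
#'
#' Draws `n_cases` spontaneous reports under the model described in
#' [synthetic_config()], optionally writes them as FAERS quarterly file
#' sets, and returns the dataset together with the realized ground truth:
#' the exact 2x2 cell counts per configured drug-event pair (computed from
#' the case-level indicators, so [build_contingency()] on the deduplicated
#' output must reproduce them exactly) and the injected duplicate report
#' ids.
#'
#' @param config a [synthetic_config()].
#' @param dir if non-`NULL`, the dataset is also written there with
#'   [write_faers_dataset()] (`split_quarters = TRUE` writes one
#'   subdirectory per quarter).
#' @param split_quarters write one file set per calendar quarter.
#' @return a [faers_dataset()]; attribute `"ground_truth"` holds
#'   `pair_counts` (a `data.table` of a/b/c/d per drug-event pair),
#'   `duplicate_primaryids`, and `n_cases`.
#' @export
simulate_faers <- function(config, dir = NULL, split_quarters = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_cases
  drug_names <- names(config$drugs)
  event_names <- names(config$events)
  g <- length(drug_names); e <- length(event_names)

  dmat <- matrix(stats::runif(n * g), n, g) < rep(config$drugs, each = n)
  colnames(dmat) <- drug_names

  # per-event tilt: max rho over the case's present drugs (1 when none)
  tilt <- matrix(1, n, e, dimnames = list(NULL, event_names))
  if (nrow(config$associations) > 0L) {
    for (k in seq_len(nrow(config$associations))) {
      gd <- config$associations$drug[k]; ev <- config$associations$event[k]
      rho <- config$associations$rho[k]
      if (!gd %in% drug_names || !ev %in% event_names) {
        stop("association refers to unknown drug/event: ", gd, " / ", ev)
      }
      idx <- dmat[, gd]
      tilt[idx, ev] <- pmax(tilt[idx, ev], rho)
      p_eff <- config$events[[ev]] * rho
      if (p_eff > 1) {
        warning(sprintf("tilted probability for pair (%s, %s) saturates at 1 (p*rho = %.2f)",
                        gd, ev, p_eff))
      }
    }
  }
  pe <- pmin(1, tilt * rep(config$events, each = n))
  emat <- matrix(stats::runif(n * e), n, e) < pe
  colnames(emat) <- event_names

  # realized ground-truth 2x2 per configured pair
  drug_tot <- colSums(dmat); event_tot <- colSums(emat)
  a_mat <- crossprod(dmat, emat)
  pair_counts <- data.table::data.table(
    drug = rep(drug_names, times = e),
    event = rep(event_names, each = g),
    a = as.vector(a_mat),
    b = rep(drug_tot, times = e) - as.vector(a_mat),
    c = rep(event_tot, each = g) - as.vector(a_mat))
  pair_counts[, "d" := n - a - b - c]

  caseid <- sprintf("%08d", seq_len(n) + 10000000L)
  primaryid <- paste0(caseid, "1")
  days <- as.integer(config$window[2] - config$window[1])
  fda_dt <- config$window[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
  event_dt <- fda_dt - sample.int(60L, n, replace = TRUE)
  sexp <- config$sex_probabilities
  sex <- sample(names(sexp), n, replace = TRUE, prob = sexp)
  bin <- sample.int(nrow(config$age_mixture), n, replace = TRUE,
                    prob = config$age_mixture$weight)
  age <- round(stats::runif(n, config$age_mixture$low[bin],
                            config$age_mixture$high[bin]))
  age_cod <- rep("YR", n)
  miss <- stats::runif(n) < config$age_missing_rate
  age[miss] <- NA_real_; age_cod[miss] <- NA_character_
  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    fda_dt = fda_dt, event_dt = event_dt, age = age, age_cod = age_cod,
    sex = sex, occr_country = "US")

  dr_idx <- which(dmat, arr.ind = TRUE)
  drug <- data.table::data.table(
    primaryid = primaryid[dr_idx[, 1]],
    drugname = drug_names[dr_idx[, 2]])
  data.table::setorder(drug, primaryid)
  drug[, "drug_seq" := seq_len(.N), by = "primaryid"]
  drug[, "role_cod" := ifelse(stats::runif(nrow(drug)) <
                                config$suspect_role_probability, "PS", "C")]
  if (!is.null(config$indication_map)) {
    drug[, "indi_pt" := unname(config$indication_map[drugname])]
  } else {
    drug[, "indi_pt" := NA_character_]
  }

  re_idx <- which(emat, arr.ind = TRUE)
  reac <- data.table::data.table(primaryid = primaryid[re_idx[, 1]],
                                 pt = event_names[re_idx[, 2]])
  data.table::setorder(reac, primaryid, pt)

  serious <- stats::runif(n) < config$serious_probability
  outc <- data.table::data.table(
    primaryid = primaryid[serious],
    outc_cod = sample(c("DE", "LT", "HO", "DS", "CA", "RI", "OT"),
                      sum(serious), replace = TRUE,
                      prob = c(0.1, 0.08, 0.45, 0.07, 0.01, 0.04, 0.25)))

  # duplicate follow-up versions: same case content, later receipt date,
  # jittered age -- only mutable fields change
  n_dup <- round(config$duplicate_version_rate * n)
  dup_ids <- character()
  if (n_dup > 0L) {
    pick <- sort(sample.int(n, n_dup))
    d2 <- demo[pick]
    v2_id <- paste0(caseid[pick], "2")
    data.table::set(d2, j = "caseversion", value = 2L)
    data.table::set(d2, j = "primaryid", value = v2_id)
    data.table::set(d2, j = "fda_dt",
                    value = d2$fda_dt + sample.int(90L, n_dup, replace = TRUE))
    jit <- which(!is.na(d2$age))
    data.table::set(d2, i = jit, j = "age",
                    value = d2$age[jit] + sample(c(-1, 0, 1), length(jit),
                                                 replace = TRUE))
    dup_ids <- v2_id
    demo <- rbind(demo, d2)
    add_children <- function(tab) {
      ch <- tab[tab$primaryid %in% paste0(caseid, "1")[pick]]
      if (nrow(ch)) ch[, "primaryid" := paste0(substr(primaryid, 1, 8), "2")]
      ch
    }
    drug <- rbind(drug, add_children(data.table::copy(drug)), fill = TRUE)
    reac <- rbind(reac, add_children(data.table::copy(reac)))
    outc <- rbind(outc, add_children(data.table::copy(outc)))
  }

  ds <- faers_dataset(demo, drug, reac, outc)
  attr(ds, "ground_truth") <- list(pair_counts = pair_counts[],
                                   duplicate_primaryids = dup_ids,
                                   n_cases = n)
  if (!is.null(dir)) {
    if (split_quarters) {
      qs <- ds$demo$quarter
      for (q in sort(unique(qs))) {
        sub <- faers_dataset(ds$demo[qs == q],
                             ds$drug[primaryid %in% ds$demo$primaryid[qs == q]],
                             ds$reac[primaryid %in% ds$demo$primaryid[qs == q]],
                             ds$outc[primaryid %in% ds$demo$primaryid[qs == q]],
                             quarter = q)
        write_faers_dataset(sub, file.path(dir, q))
      }
    } else {
      write_faers_dataset(ds, dir)
    }
  }
  ds
}

# save/restore the global RNG state so simulation is reproducible without
# clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
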