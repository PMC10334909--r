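test_that("contingency cells come from direct enumeration of case flags", {
  cases <- cases_from_flags(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, FALSE, TRUE, FALSE))
  t <- build_contingency(cases, study_drug_query(), target_event_query())
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  # degenerate: every case has both
  all4 <- cases_from_flags(rep(TRUE, 4), rep(TRUE, 4))
  t2 <- build_contingency(all4, study_drug_query(), target_event_query())
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(4, 0, 0, 0))
  expect_error(contingency_table(0, 0, 0, 0), "n >= 1")
  expect_error(contingency_table(-1, 1, 1, 1), "nonnegative")
})

test_that("contingency table equals the generator's realized ground truth", {
  cfg <- synthetic_config(n_cases = 5000, seed = 17,
    associations = data.frame(drug = "DRUG_B", event = "Event D", rho = 4))
  ds <- simulate_faers(cfg)
  cases <- deduplicate_cases(ds)
  gt <- attr(ds, "ground_truth")$pair_counts
  all_roles <- c("PS", "SS", "C", "I")
  for (pair in list(c("DRUG_B", "Event D"), c("DRUG_A", "Event A"))) {
    t <- build_contingency(cases, drug_query(pair[1], roles = all_roles),
                           event_query(pair[2]))
    g <- gt[gt$drug == pair[1] & gt$event == pair[2]]
    expect_equal(c(t$a, t$b, t$c, t$d), c(g$a, g$b, g$c, g$d))
  }
})

test_that("PRR matches hand-computed fractions and flags zero denominators", {
  expect_equal(as.numeric(prr(contingency_table(10, 10, 10, 10))), 1.0)
  expect_equal(as.numeric(prr(contingency_table(10, 90, 10, 890))), 9.0,
               tolerance = 1e-12)
  u <- prr(contingency_table(5, 5, 0, 10))
  expect_false(attr(u, "defined"))
  expect_false(is.finite(u))
})

test_that("chi-square matches hand values and the stats::chisq.test oracle", {
  t0 <- contingency_table(10, 10, 10, 10)
  expect_equal(as.numeric(chi_square(t0, yates = FALSE)), 0)
  expect_equal(as.numeric(chi_square(t0, yates = TRUE)), 0)
  t1 <- contingency_table(4, 1, 1, 4)
  expect_equal(as.numeric(chi_square(t1, yates = FALSE)), 3.6, tolerance = 1e-12)
  expect_equal(as.numeric(chi_square(t1, yates = TRUE)), 1.6, tolerance = 1e-12)
  # independent cross-check on random tables
  tabs <- random_tables(25, seed = 8)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(as.numeric(tabs[i, c("a", "b", "c", "d")]), 2, 2, byrow = TRUE)
    t <- contingency_table(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    expect_equal(as.numeric(chi_square(t, yates = FALSE)),
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = FALSE)$statistic)),
                 tolerance = 1e-10)
    expect_equal(as.numeric(chi_square(t, yates = TRUE)),
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = TRUE)$statistic)),
                 tolerance = 1e-10)
  }
  # zero marginal is undefined, flagged
  z <- chi_square(contingency_table(0, 0, 5, 5))
  expect_false(attr(z, "defined"))
})

test_that("ROR matches hand values and applies the Haldane-Anscombe correction", {
  expect_equal(ror(contingency_table(10, 10, 10, 10))$ror, 1.0)
  r <- ror(contingency_table(4, 1, 1, 4))
  expect_equal(r$ror, 16.0)
  expect_false(r$corrected)
  # hand-computed Woolf interval
  se <- sqrt(1 / 4 + 1 + 1 + 1 / 4)
  expect_equal(r$lower, exp(log(16) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$upper, exp(log(16) + 1.96 * se), tolerance = 1e-12)
  rc <- ror(contingency_table(4, 0, 1, 4))
  expect_true(rc$corrected)
  expect_equal(rc$ror, (4.5 * 4.5) / (0.5 * 1.5), tolerance = 1e-12)
})

test_that("IC uses shrunken log2 O/E with the closed-form credibility bound", {
  ic <- information_component(contingency_table(10, 10, 10, 10))
  expect_equal(ic$expected, 10)
  expect_equal(ic$ic, 0)
  expect_equal(ic$ic025, -3.3 / sqrt(10.5) - 2 / 10.5^1.5, tolerance = 1e-12)
  expect_equal(ic$ic025, -1.077, tolerance = 1e-3)
})

test_that("closed-form IC025 tracks the gamma-posterior Monte-Carlo percentile", {
  withr::with_seed(123, {
    for (cells in list(c(1, 20, 30, 500), c(5, 50, 40, 2000),
                       c(13, 2000, 965, 1642727), c(40, 10, 60, 900))) {
      t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      mc <- information_component_mc(t, n_draws = 2e5)
      expect_lt(abs(information_component(t)$ic025 - mc), 0.15)
    }
  })
})

test_that("disproportionality statistics are mutually concordant on random tables", {
  tabs <- random_tables(300, seed = 2026)
  s <- faerssignal:::dispro_core(tabs$a, tabs$b, tabs$c, tabs$d)
  dev <- tabs$a * tabs$d - tabs$b * tabs$c
  nz <- dev != 0
  # sign concordance of PRR, ROR and ad - bc
  expect_equal(sign(s$prr - 1)[nz], sign(dev)[nz])
  expect_equal(sign(s$ror - 1)[nz], sign(dev)[nz])
  # ROR further from 1 than PRR on the same side
  expect_true(all(s$ror[dev > 0] >= s$prr[dev > 0]))
  expect_true(all(s$ror[dev < 0] <= s$prr[dev < 0]))
  # credibility bound strictly below the point IC
  expect_true(all(s$ic025 < s$ic))
  # chi-square invariant under simultaneous row and column swap
  swapped <- faerssignal:::dispro_core(tabs$d, tabs$c, tabs$b, tabs$a)
  expect_equal(s$chi2, swapped$chi2, tolerance = 1e-12)
})

test_that("signal criteria use inclusive thresholds and a conjunction verdict", {
  mk <- function(prr, chi2, a, ror = 5, ic025 = 1) {
    list(prr = prr, chi2 = chi2, n_events = a, ror = ror, ic025 = ic025,
         prr_defined = TRUE, chi2_defined = TRUE)
  }
  # the published result: all three criteria independently true
  v <- evaluate_signal(mk(11.0, 107, 13, ror = 11.0, ic025 = 2.1))
  expect_true(v$evans); expect_true(v$ror_rule); expect_true(v$ic_rule)
  expect_true(v$all_three)
  # inclusive boundaries
  expect_true(evaluate_signal(mk(2.0, 4.0, 3))$evans)
  # each sub-threshold fails
  expect_false(evaluate_signal(mk(1.9, 10, 5))$evans)
  expect_false(evaluate_signal(mk(2.5, 3.9, 5))$evans)
  expect_false(evaluate_signal(mk(2.5, 10, 2))$evans)
  expect_false(evaluate_signal(mk(5, 10, 5, ror = 1.0))$ror_rule)
  expect_false(evaluate_signal(mk(5, 10, 5, ic025 = 0))$ic_rule)
  # an undefined statistic makes its criterion false with an explanation
  u <- evaluate_signal(list(prr = Inf, prr_defined = FALSE, chi2 = 10,
                            chi2_defined = TRUE, n_events = 5, ror = 2,
                            ic025 = 1))
  expect_false(u$evans)
  expect_match(u$notes, "PRR undefined", all = FALSE)
})

test_that("screening reports qualifying pairs ranked by IC025", {
  cases <- cases_from_flags(c(rep(TRUE, 8), rep(FALSE, 42)),
                            c(rep(TRUE, 6), rep(FALSE, 44)))
  scr <- screen_pairs(cases, min_a = 3)
  # the study pair and the complementary background pair both qualify
  expect_equal(nrow(scr), 2L)
  planted <- scr[scr$drug == "STUDYDRUG" & scr$event == "TARGET EVENT"]
  expect_equal(planted$a, 6)
  expect_equal(scr$drug[1], "STUDYDRUG")  # strongest IC025 ranks first
  # raising min_a drops the pair whose a falls below it
  scr2 <- screen_pairs(cases, min_a = 7)
  expect_false("STUDYDRUG" %in% scr2$drug)
  # a planted strong association ranks first over a realistic grid
  cfg <- synthetic_config(
    n_cases = 20000, seed = 29,
    drugs = stats::setNames(rep(0.03, 8), paste0("DRUG_", LETTERS[1:8])),
    events = stats::setNames(rep(0.02, 8), paste0("Event ", LETTERS[1:8])),
    associations = data.frame(drug = "DRUG_E", event = "Event C", rho = 10))
  cases2 <- deduplicate_cases(simulate_faers(cfg))
  scr3 <- screen_pairs(cases2, min_a = 3, roles = c("PS", "SS", "C", "I"))
  expect_equal(unname(unlist(scr3[1, c("drug", "event")])),
               c("DRUG_E", "EVENT C"))
  expect_true(scr3$all_three[1])
})
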