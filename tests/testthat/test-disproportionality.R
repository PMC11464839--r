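# Exact integer-arithmetic recomputation, independent of the package's
# log-scale implementation. Cells <= 1e3 keep every product below 2^53, so
# double arithmetic on the integer numerators/denominators is exact.
oracle_ror <- function(a, b, c, d) (a * d) / (b * c)
oracle_prr <- function(a, b, c, d) (a * (c + d)) / (c * (a + b))
oracle_chi2 <- function(a, b, c, d) {
  (a * d - b * c)^2 * (a + b + c + d) / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("the hand-enumerable universe yields the expected 2x2 cells", {
  rs <- example_universe()
  cs <- select_cases(rs, termset(tibble::tibble(pt_name = "microtia")),
                     filter_config())
  tab <- build_table(cs, "drugX")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 2, 1, 5))
  expect_equal(tab$n, 10L)
  # drug absent from the universe: a = c = 0, flagged
  tab0 <- build_table(cs, "no-such-drug")
  expect_equal(c(tab0$a, tab0$c), c(0, 0))
  expect_equal(tab0$b, length(cs$case_ids))
  expect_true(tab0$drug_absent)
})

test_that("contingency cells equal the generator's bookkeeping on synthetic data", {
  sim <- generate_reports(signal_sim_params(n_reports = 5000, seed = 23L))
  rs <- sim$report_set
  cs <- select_cases(rs, termset(tibble::tibble(pt_name = "eventy")),
                     filter_config(report_types = "direct"))
  tab <- build_table(cs, "drugx")
  truth <- sim$ground_truth
  has_drug <- truth$assigned$report_id[truth$assigned$generic == "drugx"]
  has_event <- unique(truth$events$report_id[truth$events$pt_name == "eventy"])
  expect_equal(tab$a, length(intersect(has_drug, has_event)))
  expect_equal(tab$a + tab$c, length(has_drug))
  expect_equal(tab$a + tab$b, length(has_event))
  expect_equal(tab$n, n_reports(rs))
  # margin conservation across drugs within one universe
  tab2 <- build_table(cs, "no-such-drug")
  expect_equal(tab$a + tab$b, tab2$a + tab2$b)
  expect_equal(tab$n, tab2$n)
})

test_that("ROR, PRR and chi-squared match hand arithmetic on pinned tables", {
  # symmetric table: ROR = 1, CI symmetric about 1 on the log scale
  rr <- ror_stats(c(10, 10, 10, 10))
  expect_equal(rr$ror, 1)
  expect_equal(rr$ci_low * rr$ci_high, 1, tolerance = 1e-12)
  # direct arithmetic oracles
  expect_equal(ror_stats(c(4, 186, 1121, 20752970))$ror,
               83011880 / 208506, tolerance = 1e-12)
  expect_equal(prr_stats(c(3, 7, 5, 85))$prr, 5.4, tolerance = 1e-12)
  expect_equal(prr_stats(c(10, 10, 10, 10))$prr, 1)
  expect_equal(chi_square(c(3, 7, 5, 85)), 220^2 * 100 / (10 * 90 * 8 * 92),
               tolerance = 1e-12)
  # independence: ad = bc gives chi-squared exactly 0
  expect_equal(chi_square(c(1, 9, 9, 81)), 0)
})

test_that("statistics agree with exact rational recomputation over random small tables", {
  set.seed(101)
  k <- matrix(sample.int(50, 4 * 2000, replace = TRUE), ncol = 4)
  for (i in seq_len(nrow(k))) {
    a <- k[i, 1]; b <- k[i, 2]; c <- k[i, 3]; d <- k[i, 4]
    expect_equal(ror_stats(c(a, b, c, d))$ror, oracle_ror(a, b, c, d),
                 tolerance = 1e-12)
    expect_equal(prr_stats(c(a, b, c, d))$prr, oracle_prr(a, b, c, d),
                 tolerance = 1e-12)
    expect_equal(chi_square(c(a, b, c, d)), oracle_chi2(a, b, c, d),
                 tolerance = 1e-12)
  }
})

test_that("zero cells error without correction and are finite with it", {
  expect_error(ror_stats(c(0, 5, 5, 5)), "zero cell")
  expect_error(prr_stats(c(3, 7, 0, 90)), "zero")
  expect_error(chi_square(c(0, 0, 5, 5)), "zero margin")
  rr <- ror_stats(c(0, 5, 5, 5), correction = TRUE)
  expect_true(is.finite(rr$ror) && rr$ror > 0)
})

test_that("ROR converges to PRR as the event grows rare in both exposure arms", {
  # ROR/PRR = (1 - c/(c+d)) / (1 - a/(a+b)): the two agree exactly when the
  # event share matches across arms and converge as both shares vanish
  rel <- vapply(1:3, function(k) {
    tab <- c(5, 5 * 10^k, 50, 50 * 10^(k + 1))
    abs(ror_stats(tab)$ror - prr_stats(tab)$prr) / ror_stats(tab)$ror
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 1e-3)
})

test_that("signal criteria implement the three rule sets with the min-case gate", {
  crit <- criteria_config()
  row <- list(a = 3, ror_ci_low = 1.5, prr = 5, prr_ci_low = 1.2, chi2 = 10)
  fl <- evaluate_signal(row, crit)
  expect_true(fl$signal)
  expect_true(fl$ror_signal)
  expect_true(fl$prr_signal)
  # a = 2 gates everything regardless of strength
  fl2 <- evaluate_signal(list(a = 2, ror_ci_low = 100, prr = 100,
                              prr_ci_low = 100, chi2 = 1e4), crit)
  expect_false(any(unlist(fl2)))
  # PRR below 2 fails the PRR rule even with large chi-squared
  fl3 <- evaluate_signal(list(a = 10, ror_ci_low = 1.5, prr = 1.9,
                              prr_ci_low = 1.2, chi2 = 50), crit)
  expect_false(fl3$prr_signal)
  expect_true(fl3$signal)
  # monotone in a and in the PRR CI lower bound
  expect_true(evaluate_signal(list(a = 3, ror_ci_low = NA, prr = NA,
                                   prr_ci_low = 1.01, chi2 = NA), crit)$signal)
  expect_false(evaluate_signal(list(a = 3, ror_ci_low = NA, prr = NA,
                                    prr_ci_low = 0.99, chi2 = NA), crit)$signal)
  expect_error(criteria_config(min_a = 0), "min_a")
})

test_that("ranking is a stable descending sort with case-count then name tie-breaks", {
  tbl <- tibble::tibble(
    generic_name = c("methimazole", "primidone", "valproic acid", "zeta", "alpha"),
    a = c(3L, 4L, 122L, 10L, 2L),
    ror = c(198.35, 397.05, 239.46, 50, 50),
    prr = c(196.25, 388.71, 236.42, 49, 49),
    chi2 = c(581, 1541, 2093, 100, 100),
    ror_ci_low = 1, ror_ci_high = 1, prr_ci_low = 1, prr_ci_high = 1,
    b = 1L, c = 1L, d = 1L, ror_signal = TRUE, prr_signal = TRUE, signal = TRUE)
  ranked <- rank_signals(tbl, by = "ror")
  expect_equal(ranked$generic_name[1:3],
               c("primidone", "valproic acid", "methimazole"))
  # equal ror: larger a first
  expect_equal(ranked$generic_name[4:5], c("zeta", "alpha"))
  # order-invariance under permutation of the input
  set.seed(7)
  for (i in 1:5) {
    perm <- tbl[sample.int(nrow(tbl)), ]
    expect_equal(rank_signals(perm, by = "ror")$generic_name,
                 ranked$generic_name)
  }
  expect_equal(nrow(rank_signals(tbl, by = "ror", top_k = 2)), 2L)
})

test_that("the per-drug signal table flags a strong injected signal", {
  sim <- generate_reports(signal_sim_params(n_reports = 20000, seed = 29L))
  cs <- select_cases(sim$report_set, termset(tibble::tibble(pt_name = "eventy")),
                     filter_config(report_types = "direct"))
  st <- signal_table(cs)
  row <- st[st$generic_name == "drugx", ]
  expect_gte(row$a, 3)
  expect_true(row$signal)
  expect_true(row$ror_signal)
  expect_gt(row$ror, 10)
  ranked <- rank_signals(st, by = "ror")
  expect_equal(ranked$generic_name[1], "drugx")
})
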