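case_set_from <- function(rs, ts = load_termset(),
                          filter = filter_config(report_types = c(
                            "direct", "expedited", "periodic", "unknown"))) {
  select_cases(rs, ts, filter)
}

test_that("sex frequencies use the case count as denominator", {
  ids <- sprintf("R%02d", 1:10)
  rs <- report_set(
    tiny_demo(ids, sex = c(rep("female", 4), rep("male", 5), "unknown")),
    tiny_drug(ids), tiny_reac(ids, pt = "microtia"), tiny_outc(ids))
  tab <- tabulate_cases(case_set_from(rs), "sex")
  expect_equal(attr(tab, "denominator"), 10L)
  expect_equal(tab$percent[match(c("female", "male", "unknown"), tab$category)],
               c(40, 50, 10))
  expect_equal(sum(tab$count), 10L)
})

test_that("age bands are half-open with 1.0 and 4.0 on the upper side", {
  ids <- sprintf("R%02d", 1:5)
  rs <- report_set(
    tiny_demo(ids, age = c(0.5, 1.0, 4.0, 12, NA)),
    tiny_drug(ids), tiny_reac(ids, pt = "microtia"), tiny_outc(ids))
  tab <- tabulate_cases(case_set_from(rs), "age_band")
  got <- setNames(tab$count, tab$category)
  expect_equal(got[c("<1", "1-4", "4-10", ">=10", "unknown")],
               c(`<1` = 1L, `1-4` = 1L, `4-10` = 1L, `>=10` = 1L, unknown = 1L))
})

test_that("counts are conserved under band refinement and match generator strata", {
  sim <- generate_reports(sim_params(n_reports = 3000, seed = 13L))
  cs <- case_set_from(sim$report_set, termset(tibble::tibble(pt_name = "nausea")))
  tab <- tabulate_cases(cs, "sex")
  expect_equal(sum(tab$count), length(cs$case_ids))
  demo <- sim$report_set$demo
  demo <- demo[demo$report_id %in% cs$case_ids, ]
  expect_equal(tab$count[tab$category == "female"], sum(demo$sex == "female"))
  # merging age bands sums counts to the same total
  ages <- tabulate_cases(cs, "age_band")
  expect_equal(sum(ages$count), length(cs$case_ids))
  # unknown variable is an error
  expect_error(tabulate_cases(cs, "shoe_size"), "unknown variable")
})

test_that("outcome tabulation can count occurrences rather than reports", {
  ids <- c("R01", "R02")
  outc <- tibble::tibble(report_id = c("R01", "R01", "R02"),
                         outcome_code = c("congenital_anomaly", "death",
                                          "congenital_anomaly"))
  rs <- report_set(tiny_demo(ids), tiny_drug(ids), tiny_reac(ids, pt = "microtia"),
                   outc)
  tab <- tabulate_cases(case_set_from(rs), "outcomes",
                        denominator_policy = "occurrences")
  expect_equal(attr(tab, "denominator"), 3L)
  expect_equal(tab$percent[tab$category == "congenital_anomaly"], 200 / 3)
})

test_that("median and quartiles follow type-7 interpolation and match the reference routine", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))
  s1 <- median_iqr(7)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(7, 7, 7))
  expect_error(median_iqr(c(NA_real_, NA_real_)), "all values missing")
  # reference oracle on lognormal draws, missing values excluded and counted
  set.seed(99)
  v <- c(rlnorm(200, log(2.75), 0.33), NA, NA)
  s2 <- median_iqr(v)
  ref <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  expect_equal(c(s2$q1, s2$median, s2$q3), ref)
  expect_equal(s2$n_nonmissing, 200L)
})

test_that("yearly counts derive percent changes and locate the largest increase", {
  ids <- sprintf("R%03d", 1:281)
  years <- c(rep(2016, 100), rep(2017, 181))
  rs <- report_set(
    tiny_demo(ids, receipt = as.Date(sprintf("%d-06-01", years))),
    tiny_drug(ids), tiny_reac(ids, pt = "microtia"), tiny_outc(ids))
  ys <- yearly_counts(case_set_from(rs))
  expect_equal(ys$count, c(100L, 181L))
  expect_equal(ys$pct_change[2], 81)
  expect_equal(attr(ys, "max_increase_pct"), 81)
  expect_equal(attr(ys, "max_increase_years"), c(2016L, 2017L))
  expect_equal(sum(ys$count), length(case_set_from(rs)$case_ids))
})

test_that("a single year yields no change entries and a planted peak is recovered", {
  ids <- c("R01", "R02")
  rs <- report_set(tiny_demo(ids, receipt = as.Date("2010-05-05")),
                   tiny_drug(ids), tiny_reac(ids, pt = "microtia"),
                   tiny_outc(ids))
  ys <- yearly_counts(case_set_from(rs))
  expect_equal(nrow(ys), 1L)
  expect_true(all(is.na(ys$pct_change)))
  # planted peak year is the argmax on synthetic data
  sim <- generate_reports(sim_params(n_reports = 4000, seed = 17L,
                                     year_range = c(2010L, 2014L)))
  cs <- case_set_from(sim$report_set, termset(tibble::tibble(pt_name = "nausea")))
  ys2 <- yearly_counts(cs)
  demo <- sim$report_set$demo
  demo <- demo[demo$report_id %in% cs$case_ids, ]
  planted_peak <- as.integer(names(which.max(table(format(demo$receipt_date, "%Y")))))
  expect_equal(ys2$year[which.max(ys2$count)], planted_peak)
})

test_that("time to onset is calendar days from first suspect-drug start to first event", {
  ids <- "R01"
  rs <- report_set(
    tiny_demo(ids),
    tiny_drug(ids, start = as.Date("2020-01-01")),
    tiny_reac(ids, event = as.Date("2020-10-01")),
    tiny_outc(ids))
  expect_equal(time_to_onset(rs)$days, 274L)
  # missing start date -> missing
  rs2 <- report_set(tiny_demo(ids), tiny_drug(ids, start = as.Date(NA)),
                    tiny_reac(ids), tiny_outc(ids))
  expect_true(is.na(time_to_onset(rs2)$days))
  # negative gap -> missing with warning
  rs3 <- report_set(tiny_demo(ids), tiny_drug(ids, start = as.Date("2021-01-01")),
                    tiny_reac(ids, event = as.Date("2020-01-01")), tiny_outc(ids))
  expect_warning(tto <- time_to_onset(rs3), "before drug start")
  expect_true(is.na(tto$days))
})

test_that("simulated onset gaps match the generator's lognormal within sampling error", {
  p <- sim_params(n_reports = 4000, seed = 21L)
  sim <- generate_reports(p)
  tto <- time_to_onset(sim$report_set)
  s <- median_iqr(tto$days)
  # lognormal(median 273): interquartile range around exp(meanlog -/+ 0.6745 sdlog)
  expect_gt(s$median, 273 * 0.95)
  expect_lt(s$median, 273 * 1.05)
  expect_gt(s$q1, 273 * exp(-0.6745 * 0.45) * 0.9)
  expect_lt(s$q3, 273 * exp(0.6745 * 0.45) * 1.1)
})
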