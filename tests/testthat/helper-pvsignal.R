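# Builders for small in-code fixtures.

tiny_demo <- function(ids, report_type = "direct", case_id = NULL,
                      version = 1L, receipt = as.Date("2018-06-01"),
                      sex = "female", age = 0.5, weight = 3, country = "US",
                      reporter = "physician") {
  tibble::tibble(
    report_id = ids, case_id = case_id %||% paste0("C", ids),
    version = version, report_type = report_type, receipt_date = receipt,
    sex = sex, age_years = age, weight_kg = weight, country = country,
    reporter = reporter
  )
}

tiny_drug <- function(ids, raw = "Depakene", generic = "valproic acid",
                      role = "primary_suspect", start = as.Date("2017-06-01")) {
  tibble::tibble(report_id = ids, drug_seq = 1L, raw_name = raw,
                 generic_name = generic, role = role, start_date = start)
}

tiny_reac <- function(ids, pt = "microtia", code = NA_integer_,
                      event = as.Date("2018-03-01")) {
  tibble::tibble(report_id = ids, pt_name = pt, pt_code = code,
                 event_date = event)
}

tiny_outc <- function(ids, code = "congenital_anomaly") {
  tibble::tibble(report_id = ids, outcome_code = code)
}

# A 10-report universe matching the hand-enumerable 2x2 example:
# 3 reports with drugX, 2 of those event-positive; 4 event-positive total.
example_universe <- function() {
  ids <- sprintf("R%02d", 1:10)
  drug_for <- c("drugX", "drugX", "drugX", "other", "other",
                "other", "other", "other", "other", "other")
  event_for <- c(TRUE, TRUE, FALSE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE)
  report_set(
    tiny_demo(ids),
    tiny_drug(ids, raw = drug_for, generic = drug_for),
    tiny_reac(ids, pt = ifelse(event_for, "microtia", "pyrexia")),
    tiny_outc(ids)
  )
}

null_sim_params <- function(n_reports = 5000, seed = 7L, drug_prob = 0.05,
                            event_prob = 0.02) {
  sim_params(
    n_reports = n_reports,
    drugs = tibble::tibble(generic = "drugx", brand = NA_character_,
                           background_prob = drug_prob),
    events = tibble::tibble(pt_name = c("eventy", "filler"),
                            background_prob = c(event_prob, 0.5)),
    signals = tibble::tibble(generic = character(), pt_name = character(),
                             rate_ratio = double()),
    report_type_mix = c(direct = 1),
    fallback_pt = "filler",
    seed = seed
  )
}

signal_sim_params <- function(n_reports = 20000, seed = 11L, rate_ratio = 50,
                              drug_prob = 0.01, event_prob = 0.002) {
  sim_params(
    n_reports = n_reports,
    drugs = tibble::tibble(generic = "drugx", brand = NA_character_,
                           background_prob = drug_prob),
    events = tibble::tibble(pt_name = c("eventy", "filler"),
                            background_prob = c(event_prob, 0.5)),
    signals = tibble::tibble(generic = "drugx", pt_name = "eventy",
                             rate_ratio = rate_ratio),
    report_type_mix = c(direct = 1),
    fallback_pt = "filler",
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
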