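#' Simulation parameters for synthetic spontaneous reports
#'
#' Defines the generative model for a FAERS-like report database: each
#' report draws one primary-suspect drug from the drug marginal (an implicit
#' background agent absorbs the remaining mass), each event PT occurs
#' independently with its background probability, multiplied by `rate_ratio`
#' (capped at 1) when an injected `(drug, event)` signal matches, and
#' demographics are drawn from the stratum mixes. Reports that draw no event
#' receive the fallback PT so every report is a well-formed ICSR. Default
#' strata mirror the clinical-characteristics profile of direct-report
#' congenital-anomaly cases: predominantly infants under 1 year, median
#' weight 2.75 kg, onset-gap median 273 days, congenital anomaly as the
#' leading outcome, and a small direct-report share typical of a spontaneous
#' reporting system.
#'
#' @param n_reports Number of reports to draw.
#' @param drugs Tibble `generic`, `brand`, `background_prob`; probabilities
#'   must sum to at most 1.
#' @param events Tibble `pt_name`, `background_prob`.
#' @param signals Tibble `generic`, `pt_name`, `rate_ratio` (may be empty).
#' @param report_type_mix,sex_mix,country_mix,reporter_mix,outcome_mix Named
#'   probability vectors summing to 1.
#' @param age_distribution List `p_unknown`, `p_infant` (mass on uniform
#'   [0, 1) years), `tail_meanlog`, `tail_sdlog` (lognormal years otherwise).
#' @param weight_distribution List `meanlog`, `sdlog`, `p_unknown` (kg).
#' @param onset_gap_distribution List `meanlog`, `sdlog` (days from drug
#'   start to event).
#' @param year_range Inclusive receipt-year range, length 2.
#' @param concomitant_prob Probability a report carries one extra
#'   concomitant drug mention (for role-filter testing).
#' @param fallback_pt PT assigned when no event is drawn.
#' @param seed Integer RNG seed; generation is fully reproducible from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(
    n_reports = 10000L,
    drugs = tibble(
      generic = c("valproic acid", "isotretinoin", "nevirapine",
                  "primidone", "methimazole", "methotrexate"),
      brand = c("Depakene", "Accutane", "Viramune",
                "Mysoline", "Tapazole", "Trexall"),
      background_prob = c(0.010, 0.005, 0.004, 0.002, 0.003, 0.010)
    ),
    events = tibble(
      pt_name = c("microtia", "anotia", "accessory auricle",
                  "pyrexia", "nausea", "drug ineffective"),
      background_prob = c(0.001, 0.0005, 0.0005, 0.05, 0.08, 0.15)
    ),
    signals = tibble(
      generic = c("valproic acid", "isotretinoin"),
      pt_name = c("microtia", "anotia"),
      rate_ratio = c(30, 20)
    ),
    report_type_mix = c(direct = 0.06, expedited = 0.74, periodic = 0.20),
    sex_mix = c(female = 0.35, male = 0.42, unknown = 0.23),
    age_distribution = list(p_unknown = 0.06, p_infant = 0.85,
                            tail_meanlog = log(9), tail_sdlog = 1),
    weight_distribution = list(meanlog = log(2.75), sdlog = 0.33, p_unknown = 0.30),
    onset_gap_distribution = list(meanlog = log(273), sdlog = 0.45),
    country_mix = c(US = 0.155, DE = 0.115, FR = 0.076, GB = 0.049,
                    DK = 0.047, Other = 0.558),
    reporter_mix = c(`other-health-professional` = 0.374, physician = 0.292,
                     consumer = 0.128, unknown = 0.099, pharmacist = 0.076,
                     lawyer = 0.031),
    outcome_mix = c(congenital_anomaly = 0.477, other_serious = 0.296,
                    hospitalization = 0.103, death = 0.068, disability = 0.032,
                    life_threatening = 0.023, required_intervention = 0.001),
    year_range = c(2004L, 2024L),
    concomitant_prob = 0,
    fallback_pt = "drug ineffective",
    seed = 1L) {
  p <- list(n_reports = as.integer(n_reports), drugs = as_tibble(drugs),
            events = as_tibble(events), signals = as_tibble(signals),
            report_type_mix = report_type_mix, sex_mix = sex_mix,
            age_distribution = age_distribution,
            weight_distribution = weight_distribution,
            onset_gap_distribution = onset_gap_distribution,
            country_mix = country_mix, reporter_mix = reporter_mix,
            outcome_mix = outcome_mix, year_range = as.integer(year_range),
            concomitant_prob = concomitant_prob, fallback_pt = fallback_pt,
            seed = as.integer(seed))
  errs <- validate_sim_params(p)
  if (length(errs)) {
    stop(paste0("invalid simulation parameters:\n  ",
                paste(errs, collapse = "\n  ")), call. = FALSE)
  }
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(length(p$n_reports) == 1 && !is.na(p$n_reports) && p$n_reports >= 1L,
      "n_reports: must be >= 1")
  chk(all(c("generic", "background_prob") %in% names(p$drugs)) && nrow(p$drugs) >= 1,
      "drugs: needs generic and background_prob")
  chk(all(p$drugs$background_prob >= 0 & p$drugs$background_prob <= 1),
      "drugs.background_prob: outside [0, 1]")
  chk(sum(p$drugs$background_prob) <= 1 + 1e-9,
      "drugs.background_prob: marginal exceeds 1")
  chk(all(c("pt_name", "background_prob") %in% names(p$events)) && nrow(p$events) >= 1,
      "events: needs pt_name and background_prob")
  chk(all(p$events$background_prob >= 0 & p$events$background_prob <= 1),
      "events.background_prob: outside [0, 1]")
  if (nrow(p$signals)) {
    chk(all(c("generic", "pt_name", "rate_ratio") %in% names(p$signals)),
        "signals: needs generic, pt_name, rate_ratio")
    chk(all(p$signals$rate_ratio > 0), "signals.rate_ratio: must be > 0")
    chk(all(p$signals$generic %in% p$drugs$generic),
        "signals.generic: not among drugs")
    chk(all(p$signals$pt_name %in% p$events$pt_name),
        "signals.pt_name: not among events")
  }
  for (nm in c("report_type_mix", "sex_mix", "country_mix", "reporter_mix",
               "outcome_mix")) {
    mix <- p[[nm]]
    chk(all(mix >= 0) && abs(sum(mix) - 1) < 1e-9,
        sprintf("%s: probabilities must be >= 0 and sum to 1", nm))
  }
  chk(all(names(p$report_type_mix) %in% REPORT_TYPES), "report_type_mix: unknown level")
  chk(all(names(p$outcome_mix) %in% OUTCOME_CODES), "outcome_mix: unknown code")
  chk(p$fallback_pt %in% p$events$pt_name, "fallback_pt: must be a listed event")
  chk(length(p$year_range) == 2 && p$year_range[1] <= p$year_range[2],
      "year_range: must be an increasing pair")
  chk(p$concomitant_prob >= 0 && p$concomitant_prob <= 1,
      "concomitant_prob: outside [0, 1]")
  errs
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

draw_mix <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic report set with known ground truth
#'
#' Draws `params$n_reports` reports under the model described in
#' [sim_params()]. The same params (including the embedded seed) always
#' produce the identical report set.
#'
#' @param params A [sim_params()].
#' @return List with `report_set` (a [report_set()]) and `ground_truth`:
#'   `assigned` (tibble `report_id`, `generic` of the planted
#'   primary-suspect drug), `events` (tibble `report_id`, `pt_name`,
#'   `fallback` flag), and `params`.
#' @export
generate_reports <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_reports
  with_seed(params$seed, {
    report_id <- sprintf("R%08d", seq_len(n))
    years <- sample(seq(params$year_range[1], params$year_range[2]), n, replace = TRUE)
    receipt <- as.Date(sprintf("%d-01-01", years)) + sample(0:364, n, replace = TRUE)

    ## drug assignment: named drugs + implicit background agent
    probs <- c(params$drugs$background_prob, 1 - sum(params$drugs$background_prob))
    gen_names <- c(params$drugs$generic, "background agent")
    brands <- c(if ("brand" %in% names(params$drugs)) params$drugs$brand
                else rep(NA_character_, nrow(params$drugs)), NA_character_)
    idx <- sample.int(length(probs), n, replace = TRUE, prob = probs)
    generic <- gen_names[idx]
    use_brand <- !is.na(brands[idx]) & stats::runif(n) < 0.5
    raw <- ifelse(use_brand, brands[idx], generic)

    ## event matrix: independent per PT given the drug
    m <- nrow(params$events)
    rr <- matrix(1, nrow = length(gen_names), ncol = m,
                 dimnames = list(gen_names, params$events$pt_name))
    if (nrow(params$signals)) {
      for (s in seq_len(nrow(params$signals))) {
        rr[params$signals$generic[s], params$signals$pt_name[s]] <-
          params$signals$rate_ratio[s]
      }
    }
    pmat <- pmin(rr[idx, , drop = FALSE] *
                   rep(params$events$background_prob, each = n), 1)
    hits <- matrix(stats::runif(n * m) < pmat, nrow = n)
    none <- rowSums(hits) == 0L
    fb <- match(params$fallback_pt, params$events$pt_name)
    hits_fb <- hits
    hits_fb[none, fb] <- TRUE

    ## demographics
    ad <- params$age_distribution
    u <- stats::runif(n)
    age <- ifelse(u < ad$p_unknown, NA_real_,
                  ifelse(u < ad$p_unknown + ad$p_infant, stats::runif(n),
                         pmin(stats::rlnorm(n, ad$tail_meanlog, ad$tail_sdlog), 95)))
    wd <- params$weight_distribution
    weight <- ifelse(stats::runif(n) < wd$p_unknown, NA_real_,
                     stats::rlnorm(n, wd$meanlog, wd$sdlog))

    gap <- round(stats::rlnorm(n, params$onset_gap_distribution$meanlog,
                               params$onset_gap_distribution$sdlog))
    start_date <- receipt - gap - sample(0:90, n, replace = TRUE)
    event_date <- start_date + gap

    demo <- tibble(
      report_id = report_id, case_id = sub("^R", "C", report_id),
      version = 1L, report_type = draw_mix(n, params$report_type_mix),
      receipt_date = receipt, sex = draw_mix(n, params$sex_mix),
      age_years = age, weight_kg = weight,
      country = draw_mix(n, params$country_mix),
      reporter = draw_mix(n, params$reporter_mix)
    )
    drugs <- tibble(report_id = report_id, drug_seq = 1L, raw_name = raw,
                    generic_name = generic, role = "primary_suspect",
                    start_date = start_date)
    if (params$concomitant_prob > 0) {
      extra <- stats::runif(n) < params$concomitant_prob
      if (any(extra)) {
        cidx <- sample.int(length(gen_names), sum(extra), replace = TRUE, prob = probs)
        drugs <- dplyr::bind_rows(drugs, tibble(
          report_id = report_id[extra], drug_seq = 2L,
          raw_name = gen_names[cidx], generic_name = gen_names[cidx],
          role = "concomitant", start_date = start_date[extra]))
      }
    }
    which_hits <- which(hits_fb, arr.ind = TRUE)
    ord <- order(which_hits[, 1], which_hits[, 2])
    which_hits <- which_hits[ord, , drop = FALSE]
    reactions <- tibble(
      report_id = report_id[which_hits[, 1]],
      pt_name = params$events$pt_name[which_hits[, 2]],
      pt_code = NA_integer_,
      event_date = event_date[which_hits[, 1]]
    )
    outcomes <- tibble(report_id = report_id,
                       outcome_code = draw_mix(n, params$outcome_mix))

    rs <- report_set(demo, drugs, reactions, outcomes,
                     provenance = list(generator = "pvsignal", seed = params$seed))
    truth_events <- tibble(
      report_id = report_id[which_hits[, 1]],
      pt_name = params$events$pt_name[which_hits[, 2]],
      fallback = !hits[cbind(which_hits[, 1], which_hits[, 2])]
    )
    list(report_set = rs,
         ground_truth = list(
           assigned = tibble(report_id = report_id, generic = generic),
           events = truth_events,
           params = params))
  })
}

#' Expected 2x2 cells under the generative model
#'
#' Closed-form expectations for one `(drug, event)` pair: with drug marginal
#' `p_d` and per-drug event probability `min(bg * rr, 1)`,
#' `E[a] = n p_d p(event | drug)`, the margins follow from the drug and
#' event marginals, and `d` by subtraction. Fallback-PT inflation (reports
#' that would otherwise have no reaction) is not modelled, so expectations
#' for the fallback PT itself understate its count.
#'
#' @param params A [sim_params()].
#' @param drug Generic name listed in `params$drugs`.
#' @param event PT name listed in `params$events`.
#' @param report_types Optional subset of report types: expectations then
#'   refer to the universe restricted to those types (type is independent of
#'   drug and event).
#' @return Named numeric `c(a, b, c, d)`; sums to the (restricted) expected
#'   universe size.
#' @export
expected_table <- function(params, drug, event, report_types = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!drug %in% params$drugs$generic) stop(sprintf("unknown drug '%s'", drug), call. = FALSE)
  ei <- match(event, params$events$pt_name)
  if (is.na(ei)) stop(sprintf("unknown event '%s'", event), call. = FALSE)
  n <- params$n_reports
  if (!is.null(report_types)) {
    n <- n * sum(params$report_type_mix[intersect(names(params$report_type_mix),
                                                  report_types)])
  }
  bg <- params$events$background_prob[ei]
  p_ev_given <- function(g) {
    s <- params$signals
    hit <- nrow(s) && any(s$generic == g & s$pt_name == event)
    if (hit) min(bg * s$rate_ratio[s$generic == g & s$pt_name == event][1], 1) else bg
  }
  p_d <- params$drugs$background_prob[params$drugs$generic == drug][1]
  gens <- c(params$drugs$generic, "background agent")
  p_all <- c(params$drugs$background_prob, 1 - sum(params$drugs$background_prob))
  p_event <- sum(p_all * vapply(gens, p_ev_given, numeric(1)))
  a <- n * p_d * p_ev_given(drug)
  b <- n * p_event - a
  cc <- n * p_d - a
  d <- n - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Operating characteristics of the signal criteria by simulation
#'
#' Repeatedly generates a report database, runs the selection and
#' disproportionality pipeline, and applies the signal criteria to each
#' injected pair (sensitivity) and each supplied null pair (false-positive
#' rate). Replicate seeds are derived deterministically from
#' `params$seed`.
#'
#' @param params A [sim_params()].
#' @param criteria A [criteria_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param null_pairs Tibble `generic`, `pt_name` of non-injected pairs to
#'   monitor (default none).
#' @param filter A [filter_config()]; default admits every report type so
#'   the whole simulated database is the universe.
#' @return List with `replicates` (tibble `rep`, `generic`, `pt_name`,
#'   `type`, `a`, `signal`) and `summary` (per type: replicate-pair count,
#'   flagged count, rate, exact binomial 95% CI).
#' @export
recovery_experiment <- function(params, criteria = criteria_config(),
                                n_reps = 20L, null_pairs = NULL,
                                filter = filter_config(report_types = REPORT_TYPES)) {
  stopifnot(inherits(params, "sim_params"), n_reps >= 1)
  pairs <- dplyr::bind_rows(
    if (nrow(params$signals)) dplyr::mutate(params$signals[c("generic", "pt_name")],
                                            type = "signal"),
    if (!is.null(null_pairs)) dplyr::mutate(as_tibble(null_pairs), type = "null")
  )
  if (is.null(pairs) || !nrow(pairs)) stop("no pairs to evaluate", call. = FALSE)
  reps <- purrr::map(seq_len(n_reps), function(r) {
    p_r <- params
    p_r$seed <- (params$seed + r) %% .Machine$integer.max
    sim <- generate_reports(p_r)
    purrr::pmap(pairs, function(generic, pt_name, type) {
      ts <- termset(tibble(pt_name = pt_name), name = pt_name)
      cs <- select_cases(sim$report_set, ts, filter)
      st <- signal_table(cs, criteria, drugs = generic)
      tibble(rep = r, generic = generic, pt_name = pt_name, type = type,
             a = st$a[1], signal = isTRUE(st$signal[1]))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- reps |>
    dplyr::summarise(n = dplyr::n(), n_flagged = sum(.data$signal), .by = "type") |>
    dplyr::mutate(rate = .data$n_flagged / .data$n)
  cis <- purrr::map2(summary$n_flagged, summary$n, function(x, nn) {
    ci <- stats::binom.test(x, nn)$conf.int
    tibble(ci_low = ci[1], ci_high = ci[2])
  }) |> dplyr::bind_rows()
  list(replicates = reps, summary = dplyr::bind_cols(summary, cis))
}
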