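#' Build a 2x2 contingency table for one drug
#'
#' For a drug--event pair over a report universe, the cells are: `a`, reports
#' with both the drug (in an admitted role) and the event; `b`, event reports
#' with other drugs; `c`, drug reports with other events; `d`, everything
#' else. Each report contributes to exactly one cell regardless of repeated
#' mentions. A drug absent from the universe yields `a = c = 0` and is
#' flagged rather than rejected.
#'
#' @param cs A `case_set` (defines cases and the universe denominator).
#' @param drug Normalized generic name.
#' @param role_filter Drug roles counted as exposure; defaults to the roles
#'   in the case set's filter.
#' @return A `pv_table2x2`: list `drug`, `a`, `b`, `c`, `d`, `n`,
#'   `drug_absent`, `policy`.
#' @export
build_table <- function(cs, drug, role_filter = NULL) {
  stopifnot(inherits(cs, "case_set"))
  role_filter <- role_filter %||% cs$filter$drug_roles
  dr <- cs$report_set$drugs
  drug_ids <- unique(dr$report_id[dr$generic_name == drug & dr$role %in% role_filter])
  drug_ids <- intersect(drug_ids, cs$universe_ids)
  n <- length(cs$universe_ids)
  n_event <- length(cs$case_ids)
  a <- length(intersect(drug_ids, cs$case_ids))
  c <- length(drug_ids) - a
  b <- n_event - a
  d <- n - a - b - c
  structure(list(drug = drug, a = a, b = b, c = c, d = d, n = n,
                 drug_absent = length(drug_ids) == 0L,
                 policy = paste0("one-report-one-cell; roles=",
                                 paste(role_filter, collapse = "+"))),
            class = "pv_table2x2")
}

#' @export
print.pv_table2x2 <- function(x, ...) {
  cat(sprintf("<2x2> %s: a=%s b=%s c=%s d=%s (n=%s)\n", x$drug,
              format(x$a), format(x$b), format(x$c), format(x$d), format(x$n)))
  invisible(x)
}

cells_of <- function(table) {
  if (inherits(table, "pv_table2x2")) {
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  } else {
    stopifnot(is.numeric(table), length(table) == 4)
    stats::setNames(as.numeric(table), c("a", "b", "c", "d"))
  }
}

apply_correction <- function(cells, correction) {
  if (correction) cells + 0.5 else cells
}

#' Reporting odds ratio with Wald 95% CI
#'
#' `ROR = ad/(bc)`; the confidence interval is
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table A `pv_table2x2` or numeric `c(a, b, c, d)`; cells may be
#'   non-integer (e.g. continuity-corrected or inverted cells).
#' @param correction Apply the Haldane--Anscombe +0.5 correction to all four
#'   cells? Default off; with it off, any zero cell is an error.
#' @return List `ror`, `ci_low`, `ci_high`.
#' @export
ror_stats <- function(table, correction = FALSE) {
  k <- apply_correction(cells_of(table), correction)
  if (any(k <= 0)) stop("zero cell: ROR undefined (enable correction)", call. = FALSE)
  ror <- (k["a"] * k["d"]) / (k["b"] * k["c"])
  se <- sqrt(sum(1 / k))
  ci <- exp(log(ror) + c(-1, 1) * 1.96 * se)
  list(ror = unname(ror), ci_low = unname(ci[1]), ci_high = unname(ci[2]))
}

#' Proportional reporting ratio with Wald 95% CI
#'
#' `PRR = a(c+d) / (c(a+b))`; the interval uses the standard log-scale
#' variance `1/a + 1/c - 1/(a+b) - 1/(c+d)`.
#'
#' @inheritParams ror_stats
#' @return List `prr`, `ci_low`, `ci_high`.
#' @export
prr_stats <- function(table, correction = FALSE) {
  k <- apply_correction(cells_of(table), correction)
  if (k["a"] <= 0 || k["c"] <= 0) {
    stop("zero a or c cell: PRR undefined (enable correction)", call. = FALSE)
  }
  prr <- k["a"] * (k["c"] + k["d"]) / (k["c"] * (k["a"] + k["b"]))
  se <- sqrt(1 / k["a"] + 1 / k["c"] - 1 / (k["a"] + k["b"]) - 1 / (k["c"] + k["d"]))
  ci <- exp(log(prr) + c(-1, 1) * 1.96 * se)
  list(prr = unname(prr), ci_low = unname(ci[1]), ci_high = unname(ci[2]))
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' `(ad - bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d))`, without continuity
#' correction. All four margins must be positive.
#'
#' @inheritParams ror_stats
#' @return Non-negative numeric.
#' @export
chi_square <- function(table, correction = FALSE) {
  k <- apply_correction(cells_of(table), correction)
  m <- c(k["a"] + k["b"], k["c"] + k["d"], k["a"] + k["c"], k["b"] + k["d"])
  if (any(m <= 0)) stop("zero margin: chi-squared undefined", call. = FALSE)
  unname((k["a"] * k["d"] - k["b"] * k["c"])^2 * sum(k) / prod(m))
}

#' Signal criteria configuration
#'
#' Three rule sets over one drug's statistics: the ROR rule (lower 95% ROR CI
#' above 1), the PRR rule (PRR at least 2 and chi-squared at least 4), and
#' the primary rule used for the headline `signal` flag (lower 95% PRR CI
#' above 1). All three additionally require at least `min_a` co-reports.
#'
#' @param min_a Minimum number of drug--event co-reports (default 3).
#' @return A `pv_criteria` list.
#' @export
criteria_config <- function(min_a = 3L) {
  min_a <- as.integer(min_a)
  if (is.na(min_a) || min_a < 1L) stop("min_a must be >= 1", call. = FALSE)
  structure(list(min_a = min_a), class = "pv_criteria")
}

#' Evaluate signal criteria for one drug
#'
#' @param stats A row-like list/tibble with `a`, `ror_ci_low`, `prr`,
#'   `prr_ci_low`, `chi2` (as produced by [signal_table()]).
#' @param criteria A [criteria_config()].
#' @return List of logicals `ror_signal`, `prr_signal`, `signal` (the
#'   headline flag: lower PRR CI > 1 and `a >= min_a`).
#' @export
evaluate_signal <- function(stats, criteria = criteria_config()) {
  stopifnot(inherits(criteria, "pv_criteria"))
  gate <- stats$a >= criteria$min_a
  list(
    ror_signal = gate & !is.na(stats$ror_ci_low) & stats$ror_ci_low > 1,
    prr_signal = gate & !is.na(stats$prr) & stats$prr >= 2 &
      !is.na(stats$chi2) & stats$chi2 >= 4,
    signal = gate & !is.na(stats$prr_ci_low) & stats$prr_ci_low > 1
  )
}

#' Disproportionality statistics for every drug in a case set
#'
#' Builds the 2x2 table and computes ROR, PRR, their 95% CIs, chi-squared and
#' the criteria flags for each candidate drug. By default candidates are the
#' generic names mentioned (in an admitted role) on at least one case; the
#' Haldane--Anscombe correction is applied per drug only when its table has a
#' zero cell, so statistics stay exact where defined.
#'
#' @param cs A `case_set`.
#' @param criteria A [criteria_config()].
#' @param drugs Candidate generic names (default: all drugs on cases).
#' @param correction `"auto"` (correct only zero-cell tables), `TRUE`
#'   (always) or `FALSE` (never; zero-cell drugs get NA statistics).
#' @return Tibble, one row per drug: `generic_name`, `a`, `b`, `c`, `d`,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `prr_ci_low`, `prr_ci_high`,
#'   `chi2`, `ror_signal`, `prr_signal`, `signal`.
#' @export
signal_table <- function(cs, criteria = criteria_config(), drugs = NULL,
                         correction = "auto") {
  stopifnot(inherits(cs, "case_set"))
  if (is.null(drugs)) {
    dr <- cs$report_set$drugs
    on_case <- dr$report_id %in% cs$case_ids & dr$role %in% cs$filter$drug_roles
    drugs <- sort(unique(dr$generic_name[on_case]))
    drugs <- drugs[!is.na(drugs)]
  }
  rows <- purrr::map(drugs, function(dg) {
    tab <- build_table(cs, dg)
    k <- cells_of(tab)
    corr <- if (identical(correction, "auto")) any(k == 0) else isTRUE(correction)
    ok <- all(k > 0) || corr
    rr <- if (ok) ror_stats(tab, correction = corr) else list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    pr <- if (ok) prr_stats(tab, correction = corr) else list(prr = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    x2 <- if (ok) chi_square(tab, correction = corr) else NA_real_
    tibble(generic_name = dg, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
           ror = rr$ror, ror_ci_low = rr$ci_low, ror_ci_high = rr$ci_high,
           prr = pr$prr, prr_ci_low = pr$ci_low, prr_ci_high = pr$ci_high,
           chi2 = x2)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(generic_name = character(), a = integer(), b = integer(),
                  c = integer(), d = integer(), ror = double(),
                  ror_ci_low = double(), ror_ci_high = double(), prr = double(),
                  prr_ci_low = double(), prr_ci_high = double(), chi2 = double())
  }
  fl <- evaluate_signal(out, criteria)
  out$ror_signal <- fl$ror_signal
  out$prr_signal <- fl$prr_signal
  out$signal <- fl$signal
  out
}

#' Rank drugs by signal strength
#'
#' Stable descending sort by the chosen statistic; ties are broken by larger
#' case count then alphabetical generic name. Input order never affects the
#' result.
#'
#' @param stats_tbl Output of [signal_table()].
#' @param by `"ror"`, `"prr"` or `"a"`.
#' @param top_k Rows to keep (default all).
#' @return The ranked (and truncated) tibble with a `rank` column.
#' @export
rank_signals <- function(stats_tbl, by = c("ror", "prr", "a"), top_k = Inf) {
  by <- match.arg(by)
  key <- stats_tbl[[by]]
  ord <- order(-ifelse(is.na(key), -Inf, key), -stats_tbl$a, stats_tbl$generic_name)
  out <- stats_tbl[ord, ]
  out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}
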