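#' Frequency table of a case characteristic
#'
#' Tabulates one demographic or administrative variable over the cases of a
#' `case_set`, mirroring the usual clinical-characteristics table. Age is
#' banded as `<1`, `1-4`, `4-10`, `>=10` (half-open: 1.0 falls in `1-4`,
#' 4.0 in `4-10`) plus `unknown`; countries keep the `top_k` most frequent
#' and pool the rest as `Other`; outcomes can be counted per occurrence
#' (several codes per report) or per report.
#'
#' @param cs A `case_set`.
#' @param variable One of `"sex"`, `"age_band"`, `"reporter"`, `"country"`,
#'   `"outcomes"`.
#' @param denominator_policy `"cases"` (percent of reports) or
#'   `"occurrences"` (percent of outcome occurrences; outcomes only).
#' @param top_k Number of named countries before pooling into `Other`.
#' @return Tibble `category`, `count`, `percent`, with the denominator in
#'   attribute `denominator`.
#' @export
tabulate_cases <- function(cs, variable, denominator_policy = c("cases", "occurrences"),
                           top_k = 5L) {
  stopifnot(inherits(cs, "case_set"))
  denominator_policy <- match.arg(denominator_policy)
  demo <- cs$report_set$demo
  demo <- demo[demo$report_id %in% cs$case_ids, ]

  val <- switch(variable,
    sex = demo$sex,
    reporter = demo$reporter,
    country = {
      x <- ifelse(is.na(demo$country), "Unknown", demo$country)
      top <- utils::head(setdiff(names(sort(table(x), decreasing = TRUE)), "Unknown"), top_k)
      ifelse(x %in% top, x, ifelse(x == "Unknown", "Unknown", "Other"))
    },
    age_band = age_band(demo$age_years),
    outcomes = NULL,
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  )

  if (variable == "outcomes") {
    oc <- cs$report_set$outcomes
    oc <- oc[oc$report_id %in% cs$case_ids, ]
    counts <- dplyr::count(oc, category = .data$outcome_code, name = "count")
    denom <- if (denominator_policy == "occurrences") nrow(oc) else length(cs$case_ids)
  } else {
    counts <- dplyr::count(tibble(category = val), .data$category, name = "count")
    denom <- nrow(demo)
  }
  counts <- dplyr::arrange(counts, dplyr::desc(.data$count), .data$category)
  counts$percent <- 100 * counts$count / denom
  attr(counts, "denominator") <- denom
  counts
}

age_band <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "unknown",
    age < 1 ~ "<1",
    age < 4 ~ "1-4",
    age < 10 ~ "4-10",
    TRUE ~ ">=10"
  )
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation (R's default type 7); missing values
#' are excluded and counted.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @return List `median`, `q1`, `q3`, `n_nonmissing`.
#' @export
median_iqr <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values missing", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n_nonmissing = length(v))
}

#' Yearly case counts and percent changes
#'
#' Counts cases per receipt year and derives the year-over-year percent
#' change `100 * (n_y - n_{y-1}) / n_{y-1}`; the largest increase is
#' reported in the attributes `max_increase_pct` and `max_increase_years`.
#' Years with no cases between the first and last observed year are filled
#' with zero so changes refer to consecutive calendar years.
#'
#' @param cs A `case_set`.
#' @return Tibble `year`, `count`, `pct_change` (NA for the first year).
#' @export
yearly_counts <- function(cs) {
  stopifnot(inherits(cs, "case_set"))
  demo <- cs$report_set$demo
  demo <- demo[demo$report_id %in% cs$case_ids & !is.na(demo$receipt_date), ]
  if (!nrow(demo)) {
    out <- tibble(year = integer(), count = integer(), pct_change = double())
    attr(out, "max_increase_pct") <- NA_real_
    return(out)
  }
  yr <- as.integer(format(demo$receipt_date, "%Y"))
  rng <- seq(min(yr), max(yr))
  cnt <- as.integer(table(factor(yr, levels = rng)))
  prev <- dplyr::lag(cnt)
  pct <- ifelse(is.na(prev) | prev == 0, NA_real_, 100 * (cnt - prev) / prev)
  out <- tibble(year = rng, count = cnt, pct_change = pct)
  if (any(!is.na(pct))) {
    i <- which.max(pct)
    attr(out, "max_increase_pct") <- pct[i]
    attr(out, "max_increase_years") <- c(rng[i] - 1L, rng[i])
  } else {
    attr(out, "max_increase_pct") <- NA_real_
  }
  out
}

#' Time to onset per report
#'
#' Days from the earliest primary-suspect drug start date to the earliest
#' reaction event date. Missing when either date is absent; a negative
#' difference (event recorded before drug start, a data-entry artifact) is
#' returned as missing with a warning.
#'
#' @param rs A `report_set`.
#' @param report_ids Optional subset of report ids (default: all).
#' @return Tibble `report_id`, `days` (integer or NA) in `report_id` order.
#' @export
time_to_onset <- function(rs, report_ids = NULL) {
  stopifnot(inherits(rs, "report_set"))
  ids <- sort(report_ids %||% rs$demo$report_id)
  min_date <- function(x) if (length(x)) min(x) else as.Date(NA)
  starts <- rs$drugs |>
    dplyr::filter(.data$role == "primary_suspect", !is.na(.data$start_date),
                  .data$report_id %in% ids) |>
    dplyr::summarise(start = min_date(.data$start_date), .by = "report_id")
  events <- rs$reactions |>
    dplyr::filter(!is.na(.data$event_date), .data$report_id %in% ids) |>
    dplyr::summarise(event = min_date(.data$event_date), .by = "report_id")
  out <- tibble(report_id = ids) |>
    dplyr::left_join(starts, by = "report_id") |>
    dplyr::left_join(events, by = "report_id")
  days <- as.integer(out$event - out$start)
  neg <- !is.na(days) & days < 0
  if (any(neg)) {
    warning(sprintf("%d report(s) with event before drug start; treated as missing",
                    sum(neg)), call. = FALSE)
    days[neg] <- NA_integer_
  }
  tibble(report_id = out$report_id, days = days)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
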