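#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

REPORT_TYPES <- c("direct", "expedited", "periodic", "unknown")
SEX_LEVELS <- c("female", "male", "unknown")
REPORTER_LEVELS <- c("physician", "pharmacist", "other-health-professional",
                     "consumer", "lawyer", "unknown")
DRUG_ROLES <- c("primary_suspect", "secondary_suspect", "concomitant", "interacting")
OUTCOME_CODES <- c("congenital_anomaly", "hospitalization", "death", "disability",
                   "life_threatening", "required_intervention", "other_serious")

demo_cols <- c("report_id", "case_id", "version", "report_type", "receipt_date",
               "sex", "age_years", "weight_kg", "country", "reporter")
drug_cols <- c("report_id", "drug_seq", "raw_name", "generic_name", "role",
               "start_date")
reac_cols <- c("report_id", "pt_name", "pt_code", "event_date")
outc_cols <- c("report_id", "outcome_code")

#' Construct a report set
#'
#' A `report_set` is the in-memory form of a linked spontaneous-report
#' database extract: one row per individual case safety report (ICSR) in
#' `demo`, with one-to-many `drugs`, `reactions` and `outcomes` tables keyed
#' by `report_id`. The constructor enforces the linking invariants (unique
#' report ids; every report has at least one drug mention and one reaction)
#' and fails rather than silently repairing — use [read_reports()] for
#' quarantine-and-continue semantics on raw files.
#'
#' @param demo Tibble with columns `report_id`, `case_id`, `version`,
#'   `report_type`, `receipt_date`, `sex`, `age_years`, `weight_kg`,
#'   `country`, `reporter`.
#' @param drugs Tibble with columns `report_id`, `drug_seq`, `raw_name`,
#'   `generic_name`, `role`, `start_date`.
#' @param reactions Tibble with columns `report_id`, `pt_name`, `pt_code`,
#'   `event_date`.
#' @param outcomes Tibble with columns `report_id`, `outcome_code`.
#' @param quarantine Tibble of rejected rows (`table`, `line`, `report_id`,
#'   `reason`); usually produced by [read_reports()].
#' @param provenance Named list recording source paths, dialect and counts.
#'
#' @return A `report_set` object.
#' @export
report_set <- function(demo, drugs, reactions, outcomes,
                       quarantine = empty_quarantine(), provenance = list()) {
  demo <- as_tibble(demo)[demo_cols]
  drugs <- as_tibble(drugs)[drug_cols]
  reactions <- as_tibble(reactions)[reac_cols]
  outcomes <- as_tibble(outcomes)[outc_cols]
  if (anyDuplicated(demo$report_id)) {
    stop("duplicate report_id in demographics table", call. = FALSE)
  }
  missing_drug <- setdiff(demo$report_id, drugs$report_id)
  missing_reac <- setdiff(demo$report_id, reactions$report_id)
  if (length(missing_drug) || length(missing_reac)) {
    stop(sprintf("reports without drug mentions (%d) or reactions (%d); use read_reports() to quarantine",
                 length(missing_drug), length(missing_reac)), call. = FALSE)
  }
  bad_age <- !is.na(demo$age_years) & demo$age_years < 0
  bad_wt <- !is.na(demo$weight_kg) & demo$weight_kg <= 0
  if (any(bad_age) || any(bad_wt)) {
    stop("age_years must be non-negative and weight_kg positive when present",
         call. = FALSE)
  }
  ord <- order(demo$report_id)
  structure(
    list(
      demo = demo[ord, ],
      drugs = dplyr::arrange(drugs, .data$report_id, .data$drug_seq),
      reactions = dplyr::arrange(reactions, .data$report_id, .data$pt_name),
      outcomes = dplyr::arrange(outcomes, .data$report_id, .data$outcome_code),
      quarantine = quarantine,
      provenance = provenance
    ),
    class = "report_set"
  )
}

empty_quarantine <- function() {
  tibble(table = character(), line = integer(),
         report_id = character(), reason = character())
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d drug mentions, %d reactions, %d outcomes, %d quarantined\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes),
              nrow(x$quarantine)))
  invisible(x)
}

#' Number of reports in a report set
#' @param rs A `report_set`.
#' @return Integer count of linked reports.
#' @export
n_reports <- function(rs) nrow(rs$demo)

## ---- reading -------------------------------------------------------------

read_table_raw <- function(path, dialect, cols) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  tb <- readr::read_delim(path, delim = dialect$delimiter,
                          col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE,
                          show_col_types = FALSE)
  missing <- setdiff(cols, names(tb))
  if (length(missing)) {
    stop(sprintf("table '%s' lacks required columns: %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tb <- tb[cols]
  tb[] <- lapply(tb, function(v) ifelse(is.na(v) | v == "", NA_character_, v))
  tb$.line <- seq_len(nrow(tb)) + 1L  # header is line 1
  tb
}

parse_enum <- function(x, levels, unknown_ok = FALSE) {
  out <- ifelse(is.na(x) & unknown_ok, "unknown", x)
  ok <- out %in% levels
  list(value = ifelse(ok, out, NA_character_), ok = ok)
}

parse_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Read linked report tables
#'
#' Reads the four delimited tables of a FAERS-style extract (demographics,
#' drug mentions, reactions, outcomes), validates each row, joins them on
#' `report_id`, and assembles a [report_set]. Malformed rows and reports that
#' cannot be fully linked (no demographics row, no drug mention, or no
#' reaction) are quarantined with a reason and line number rather than
#' silently dropped; a duplicate `report_id` in the demographics table is a
#' hard error.
#'
#' @param demo_path,drug_path,reac_path,outc_path Paths to the four tables.
#' @param dialect A [report_dialect()]; defaults to [csv_dialect()].
#' @return A `report_set`; its `quarantine` element lists every rejected row
#'   and its `provenance` records paths, dialect and row counts.
#' @export
read_reports <- function(demo_path, drug_path, reac_path, outc_path,
                         dialect = csv_dialect()) {
  stopifnot(inherits(dialect, "pv_dialect"))
  demo_raw <- read_table_raw(demo_path, dialect, demo_cols)
  drug_raw <- read_table_raw(drug_path, dialect, drug_cols)
  reac_raw <- read_table_raw(reac_path, dialect, reac_cols)
  outc_raw <- read_table_raw(outc_path, dialect, outc_cols)

  quar <- list()
  note <- function(table, lines, ids, reason) {
    if (length(lines)) {
      quar[[length(quar) + 1L]] <<- tibble(
        table = table, line = as.integer(lines),
        report_id = ifelse(is.na(ids), "", ids), reason = reason)
    }
  }

  ## demographics ----
  d <- demo_raw
  if (anyDuplicated(stats::na.omit(d$report_id))) {
    stop("duplicate report_id in demographics table", call. = FALSE)
  }
  version <- suppressWarnings(as.integer(d$version))
  rtype <- parse_enum(d$report_type, REPORT_TYPES, unknown_ok = TRUE)
  sex <- parse_enum(d$sex, SEX_LEVELS, unknown_ok = TRUE)
  reporter <- parse_enum(d$reporter, REPORTER_LEVELS, unknown_ok = TRUE)
  receipt <- parse_dialect_date(d$receipt_date, dialect)
  age <- parse_num(d$age_years)
  wt <- parse_num(d$weight_kg)
  bad <- dplyr::case_when(
    is.na(d$report_id) ~ "missing report_id",
    is.na(d$case_id) ~ "missing case_id",
    is.na(version) | version < 1L ~ "invalid version",
    !rtype$ok ~ "invalid report_type",
    !sex$ok ~ "invalid sex",
    !reporter$ok ~ "invalid reporter",
    !is.na(d$receipt_date) & is.na(receipt) ~ "unparseable receipt_date",
    !is.na(d$age_years) & (is.na(age) | age < 0) ~ "invalid age_years",
    !is.na(d$weight_kg) & (is.na(wt) | wt <= 0) ~ "invalid weight_kg",
    TRUE ~ NA_character_
  )
  note("demo", d$.line[!is.na(bad)], d$report_id[!is.na(bad)], bad[!is.na(bad)])
  keep <- is.na(bad)
  demo <- tibble(
    report_id = d$report_id[keep], case_id = d$case_id[keep],
    version = version[keep], report_type = rtype$value[keep],
    receipt_date = receipt[keep], sex = sex$value[keep],
    age_years = age[keep], weight_kg = wt[keep],
    country = d$country[keep], reporter = reporter$value[keep]
  )

  ## drug mentions ----
  g <- drug_raw
  role <- parse_enum(g$role, DRUG_ROLES)
  start <- parse_dialect_date(g$start_date, dialect)
  seq_no <- suppressWarnings(as.integer(g$drug_seq))
  bad <- dplyr::case_when(
    is.na(g$report_id) ~ "missing report_id",
    is.na(g$raw_name) ~ "missing raw_name",
    !role$ok ~ "invalid role",
    !is.na(g$start_date) & is.na(start) ~ "unparseable start_date",
    !(g$report_id %in% demo$report_id) ~ "no demographics row",
    TRUE ~ NA_character_
  )
  note("drug", g$.line[!is.na(bad)], g$report_id[!is.na(bad)], bad[!is.na(bad)])
  keep <- is.na(bad)
  drugs <- tibble(
    report_id = g$report_id[keep],
    drug_seq = ifelse(is.na(seq_no[keep]), seq_along(which(keep)), seq_no[keep]),
    raw_name = g$raw_name[keep], generic_name = g$generic_name[keep],
    role = role$value[keep], start_date = start[keep]
  )

  ## reactions ----
  r <- reac_raw
  code <- suppressWarnings(as.integer(r$pt_code))
  edate <- parse_dialect_date(r$event_date, dialect)
  bad <- dplyr::case_when(
    is.na(r$report_id) ~ "missing report_id",
    is.na(r$pt_name) ~ "missing pt_name",
    !is.na(r$pt_code) & (is.na(code) | code <= 0L) ~ "invalid pt_code",
    !is.na(r$event_date) & is.na(edate) ~ "unparseable event_date",
    !(r$report_id %in% demo$report_id) ~ "no demographics row",
    TRUE ~ NA_character_
  )
  note("reac", r$.line[!is.na(bad)], r$report_id[!is.na(bad)], bad[!is.na(bad)])
  keep <- is.na(bad)
  reactions <- tibble(
    report_id = r$report_id[keep], pt_name = r$pt_name[keep],
    pt_code = code[keep], event_date = edate[keep]
  )

  ## outcomes ----
  o <- outc_raw
  oc <- parse_enum(o$outcome_code, OUTCOME_CODES)
  bad <- dplyr::case_when(
    is.na(o$report_id) ~ "missing report_id",
    !oc$ok ~ "invalid outcome_code",
    !(o$report_id %in% demo$report_id) ~ "no demographics row",
    TRUE ~ NA_character_
  )
  note("outc", o$.line[!is.na(bad)], o$report_id[!is.na(bad)], bad[!is.na(bad)])
  keep <- is.na(bad)
  outcomes <- tibble(report_id = o$report_id[keep], outcome_code = oc$value[keep])

  ## linking: every report needs >= 1 drug and >= 1 reaction ----
  no_drug <- setdiff(demo$report_id, drugs$report_id)
  no_reac <- setdiff(demo$report_id, reactions$report_id)
  drop_ids <- union(no_drug, no_reac)
  if (length(drop_ids)) {
    lines <- demo_raw$.line[match(drop_ids, demo_raw$report_id)]
    reason <- ifelse(drop_ids %in% no_drug & drop_ids %in% no_reac,
                     "no drug mentions; no reactions",
                     ifelse(drop_ids %in% no_drug, "no drug mentions", "no reactions"))
    note("demo", lines, drop_ids, reason)
    demo <- demo[!demo$report_id %in% drop_ids, ]
    drugs <- drugs[!drugs$report_id %in% drop_ids, ]
    reactions <- reactions[!reactions$report_id %in% drop_ids, ]
    outcomes <- outcomes[!outcomes$report_id %in% drop_ids, ]
  }

  quarantine <- if (length(quar)) dplyr::bind_rows(quar) else empty_quarantine()
  report_set(
    demo, drugs, reactions, outcomes, quarantine = quarantine,
    provenance = list(
      paths = c(demo = demo_path, drug = drug_path, reac = reac_path, outc = outc_path),
      dialect = dialect,
      rows_read = c(demo = nrow(demo_raw), drug = nrow(drug_raw),
                    reac = nrow(reac_raw), outc = nrow(outc_raw)),
      n_quarantined = nrow(quarantine)
    )
  )
}

## ---- writing -------------------------------------------------------------

format_real <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Write a report set to linked delimited tables
#'
#' Emits the four tables (`demo`, `drug`, `reac`, `outc`) in the given
#' dialect so that [read_reports()] inverts the write exactly.
#'
#' @param rs A `report_set`.
#' @param out_dir Output directory (created if absent).
#' @param dialect A [report_dialect()].
#' @param overwrite Overwrite existing files? Default `FALSE` (collision is
#'   an error).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_reports <- function(rs, out_dir, dialect = csv_dialect(), overwrite = FALSE) {
  stopifnot(inherits(rs, "report_set"), inherits(dialect, "pv_dialect"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, paste0(c("demo", "drug", "reac", "outc"), ".",
                                     dialect$extension))
  names(paths) <- c("demo", "drug", "reac", "outc")
  if (!overwrite && any(file.exists(paths))) {
    stop("output files exist; pass overwrite = TRUE", call. = FALSE)
  }
  d <- rs$demo
  demo_out <- tibble(
    report_id = d$report_id, case_id = d$case_id,
    version = as.character(d$version), report_type = d$report_type,
    receipt_date = format_dialect_date(d$receipt_date, dialect),
    sex = d$sex, age_years = format_real(d$age_years),
    weight_kg = format_real(d$weight_kg), country = d$country,
    reporter = d$reporter
  )
  g <- rs$drugs
  drug_out <- tibble(
    report_id = g$report_id, drug_seq = as.character(g$drug_seq),
    raw_name = g$raw_name, generic_name = g$generic_name, role = g$role,
    start_date = format_dialect_date(g$start_date, dialect)
  )
  r <- rs$reactions
  reac_out <- tibble(
    report_id = r$report_id, pt_name = r$pt_name,
    pt_code = ifelse(is.na(r$pt_code), NA_character_, as.character(r$pt_code)),
    event_date = format_dialect_date(r$event_date, dialect)
  )
  o <- rs$outcomes
  outc_out <- tibble(report_id = o$report_id, outcome_code = o$outcome_code)

  readr::write_delim(demo_out, paths["demo"], delim = dialect$delimiter, na = "")
  readr::write_delim(drug_out, paths["drug"], delim = dialect$delimiter, na = "")
  readr::write_delim(reac_out, paths["reac"], delim = dialect$delimiter, na = "")
  readr::write_delim(outc_out, paths["outc"], delim = dialect$delimiter, na = "")
  invisible(paths)
}

## ---- case-version deduplication ------------------------------------------

#' Collapse case versions to the latest report
#'
#' Spontaneous-report databases version follow-up reports under a shared
#' `case_id`. This keeps, for each case, only the report with the highest
#' `version` (ties broken by highest `report_id`), dropping superseded
#' versions from all four tables. Off the default pipeline path: the analysis
#' unit is the ICSR, and deduplication is opt-in.
#'
#' @param rs A `report_set`.
#' @return A `report_set` with one report per `case_id`; the number removed
#'   is recorded in `provenance$n_deduplicated`.
#' @export
deduplicate_cases <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  keep_ids <- rs$demo |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$version), dplyr::desc(.data$report_id)) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE) |>
    dplyr::pull("report_id")
  removed <- nrow(rs$demo) - length(keep_ids)
  prov <- rs$provenance
  prov$n_deduplicated <- removed
  report_set(
    rs$demo[rs$demo$report_id %in% keep_ids, ],
    rs$drugs[rs$drugs$report_id %in% keep_ids, ],
    rs$reactions[rs$reactions$report_id %in% keep_ids, ],
    rs$outcomes[rs$outcomes$report_id %in% keep_ids, ],
    quarantine = rs$quarantine, provenance = prov
  )
}
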