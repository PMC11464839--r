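#' Load a preferred-term case definition
#'
#' A term set is a list of MedDRA preferred terms (PT name, optional PT code)
#' defining the adverse event under study. With no path, the bundled
#' definition of congenital external-ear anomalies (10 PTs, from accessory
#' auricle to protuberant ear) is loaded. PT names are case-folded and are
#' the primary match key; codes, where present, are accepted as an
#' alternative key.
#'
#' @param path Path to a term-set YAML (`name`, `terms:` list of
#'   `pt_name`/`pt_code` pairs), or `NULL` for the bundled default.
#' @return A `pv_termset`: tibble of `pt_name`, `pt_code` with a `name`
#'   attribute.
#' @export
load_termset <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "termset_external_ear.yaml", package = "pvsignal")
  }
  if (!file.exists(path)) stop(sprintf("term-set file '%s' not found", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$terms) || length(y$terms) == 0L) {
    stop("term set is empty", call. = FALSE)
  }
  tb <- tibble(
    pt_name = tolower(trimws(vapply(y$terms, function(t) as.character(t$pt_name), character(1)))),
    pt_code = vapply(y$terms, function(t) {
      if (is.null(t$pt_code)) NA_integer_ else as.integer(t$pt_code)
    }, integer(1))
  )
  termset(tb, name = if (is.null(y$name)) basename(path) else y$name)
}

#' @rdname load_termset
#' @param entries Tibble or data frame with `pt_name` and optionally `pt_code`.
#' @param name Label for the term set.
#' @export
termset <- function(entries, name = "termset") {
  entries <- as_tibble(entries)
  if (!nrow(entries)) stop("term set is empty", call. = FALSE)
  if (!"pt_code" %in% names(entries)) entries$pt_code <- NA_integer_
  entries$pt_name <- tolower(trimws(entries$pt_name))
  if (any(entries$pt_name == "")) stop("empty pt_name in term set", call. = FALSE)
  if (anyDuplicated(entries$pt_name)) {
    stop("duplicate pt_name (case-insensitive) in term set", call. = FALSE)
  }
  structure(entries[c("pt_name", "pt_code")], name = name,
            class = c("pv_termset", class(entries)))
}

#' Match reports against a term set
#'
#' A report is event-positive when any of its reactions matches the term set:
#' case-insensitive PT-name equality, or PT-code equality when both the
#' reaction and the term carry a code.
#'
#' @param rs A `report_set`.
#' @param ts A `pv_termset`.
#' @return Tibble `report_id`, `matched` (logical), one row per report in
#'   `rs`, in `report_id` order.
#' @export
match_event <- function(rs, ts) {
  stopifnot(inherits(rs, "report_set"), inherits(ts, "pv_termset"))
  re <- rs$reactions
  name_hit <- tolower(trimws(re$pt_name)) %in% ts$pt_name
  codes <- ts$pt_code[!is.na(ts$pt_code)]
  code_hit <- !is.na(re$pt_code) & re$pt_code %in% codes
  hit_ids <- unique(re$report_id[name_hit | code_hit])
  tibble(report_id = rs$demo$report_id,
         matched = rs$demo$report_id %in% hit_ids)
}

#' Load a drug synonym map
#'
#' Maps raw/brand drug names (case-folded) to generic names. With no path,
#' the bundled static map (brand and generic spellings for the drugs tracked
#' by the pipeline) is loaded; it stands in for a live drug-dictionary
#' lookup.
#'
#' @param path CSV with columns `raw_name`, `generic_name`, or `NULL` for the
#'   bundled map.
#' @return A named character vector (names are case-folded raw names).
#' @export
load_synonym_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_synonyms.csv", package = "pvsignal")
  }
  tb <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(c("raw_name", "generic_name") %in% names(tb))) {
    stop("synonym map needs columns raw_name, generic_name", call. = FALSE)
  }
  if (any(is.na(tb$generic_name) | tb$generic_name == "")) {
    stop("synonym map has empty generic names", call. = FALSE)
  }
  stats::setNames(tolower(trimws(tb$generic_name)), tolower(trimws(tb$raw_name)))
}

#' Normalize drug mentions to generic names
#'
#' Sets each drug mention's `generic_name` by case-folded lookup of its
#' `raw_name` in the synonym map. Mentions whose raw name has no mapping are
#' removed and logged (the manual-elimination policy for unresolvable names);
#' reports left with no drug mentions are removed from the set and logged.
#' Applying the map twice is a no-op.
#'
#' @param rs A `report_set`.
#' @param synonym_map Named character vector from [load_synonym_map()].
#' @return List with elements `report_set` (normalized) and `dropped` (tibble
#'   `kind`, `report_id`, `raw_name`, `reason`).
#' @export
normalize_drugs <- function(rs, synonym_map = load_synonym_map()) {
  stopifnot(inherits(rs, "report_set"))
  key <- tolower(trimws(rs$drugs$raw_name))
  generic <- unname(synonym_map[key])
  unmatched <- is.na(generic)
  dropped_mentions <- tibble(
    kind = "drug_mention",
    report_id = rs$drugs$report_id[unmatched],
    raw_name = rs$drugs$raw_name[unmatched],
    reason = "no synonym mapping"
  )
  drugs <- rs$drugs[!unmatched, ]
  drugs$generic_name <- generic[!unmatched]

  empty_ids <- setdiff(rs$demo$report_id, drugs$report_id)
  dropped_reports <- tibble(
    kind = "report", report_id = empty_ids, raw_name = NA_character_,
    reason = "no resolvable drug mentions"
  )
  prov <- rs$provenance
  prov$n_dropped_mentions <- nrow(dropped_mentions)
  prov$n_dropped_reports <- length(empty_ids)
  keep <- !(rs$demo$report_id %in% empty_ids)
  out <- report_set(
    rs$demo[keep, ], drugs,
    rs$reactions[rs$reactions$report_id %in% rs$demo$report_id[keep], ],
    rs$outcomes[rs$outcomes$report_id %in% rs$demo$report_id[keep], ],
    quarantine = rs$quarantine, provenance = prov
  )
  list(report_set = out, dropped = dplyr::bind_rows(dropped_mentions, dropped_reports))
}

#' Report-level filter configuration
#'
#' Defaults follow the study design for direct-report analyses: only reports
#' submitted straight to the regulator (`direct`), only drugs the reporter
#' marked primary suspect, no seriousness requirement (every outcome code in
#' the schema is already a serious outcome; the switch additionally requires
#' at least one recorded outcome).
#'
#' @param report_types Report types admitted to the universe.
#' @param drug_roles Drug roles considered exposure.
#' @param require_outcome_serious Require at least one recorded outcome code?
#' @return A `pv_filter` list.
#' @export
filter_config <- function(report_types = "direct",
                          drug_roles = "primary_suspect",
                          require_outcome_serious = FALSE) {
  report_types <- match.arg(report_types, REPORT_TYPES, several.ok = TRUE)
  drug_roles <- match.arg(drug_roles, DRUG_ROLES, several.ok = TRUE)
  structure(list(report_types = report_types, drug_roles = drug_roles,
                 require_outcome_serious = isTRUE(require_outcome_serious)),
            class = "pv_filter")
}

#' Select event-positive cases and the comparison universe
#'
#' The universe (denominator set) is every report whose type passes the
#' filter. Cases are universe reports that (i) carry at least one drug
#' mention in an admitted role, (ii) match the term set, and (iii) if
#' required, have at least one recorded outcome.
#'
#' @param rs A `report_set` (drug names already normalized).
#' @param ts A `pv_termset`.
#' @param filter A [filter_config()].
#' @return A `case_set`: list with `case_ids`, `universe_ids`, `report_set`,
#'   `termset`, `filter`.
#' @export
select_cases <- function(rs, ts, filter = filter_config()) {
  stopifnot(inherits(rs, "report_set"), inherits(ts, "pv_termset"),
            inherits(filter, "pv_filter"))
  universe_ids <- rs$demo$report_id[rs$demo$report_type %in% filter$report_types]
  if (!length(universe_ids)) {
    stop("no reports pass the report-type filter: denominator undefined", call. = FALSE)
  }
  role_ids <- unique(rs$drugs$report_id[rs$drugs$role %in% filter$drug_roles])
  matched <- match_event(rs, ts)
  event_ids <- matched$report_id[matched$matched]
  case_ids <- intersect(universe_ids, intersect(role_ids, event_ids))
  if (filter$require_outcome_serious) {
    case_ids <- intersect(case_ids, unique(rs$outcomes$report_id))
  }
  structure(list(case_ids = sort(case_ids), universe_ids = sort(universe_ids),
                 report_set = rs, termset = ts, filter = filter),
            class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %d cases / %d universe reports (term set '%s')\n",
              length(x$case_ids), length(x$universe_ids), attr(x$termset, "name")))
  invisible(x)
}
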