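#' Validate a study configuration
#'
#' A study config (YAML file or list) names the four input tables and their
#' dialect, the term set, the synonym map, the report filters, the signal
#' criteria, the ranking rule and the output directory. Missing optional
#' blocks receive the study defaults: direct reports only, primary-suspect
#' drugs only, `min_a = 3`, ranking by ROR with `top_k = 50`. Every failure
#' is reported with its field path; cross-referenced files must exist.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated `study_config` list.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config), call. = FALSE)
    yaml::read_yaml(config)
  } else config
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  inp <- cfg$inputs
  chk(!is.null(inp), "inputs: block required")
  for (k in c("demo", "drug", "reac", "outc")) {
    chk(!is.null(inp[[k]]) && file.exists(inp[[k]]),
        sprintf("inputs.%s: missing or file not found", k))
  }
  dialect <- switch(cfg$dialect %||% "csv",
                    csv = csv_dialect(), faers = faers_dialect(),
                    { errs <- c(errs, "dialect: must be 'csv' or 'faers'"); NULL })

  termset_path <- cfg$termset
  if (!is.null(termset_path)) chk(file.exists(termset_path), "termset: file not found")
  synonym_path <- cfg$synonym_map
  if (!is.null(synonym_path)) chk(file.exists(synonym_path), "synonym_map: file not found")

  flt <- cfg$filters %||% list()
  filter <- tryCatch(
    filter_config(
      report_types = flt$report_types %||% "direct",
      drug_roles = flt$drug_roles %||% "primary_suspect",
      require_outcome_serious = flt$require_outcome_serious %||% FALSE),
    error = function(e) { errs <<- c(errs, paste0("filters: ", conditionMessage(e))); NULL })

  crit <- cfg$criteria %||% list()
  criteria <- tryCatch(criteria_config(min_a = crit$min_a %||% 3L),
                       error = function(e) { errs <<- c(errs, paste0("criteria.min_a: ", conditionMessage(e))); NULL })

  rk <- cfg$ranking %||% list()
  by <- rk$by %||% "ror"
  chk(by %in% c("ror", "prr", "a"), "ranking.by: must be ror, prr or a")
  top_k <- rk$top_k %||% 50L
  chk(is.numeric(top_k) && top_k >= 1, "ranking.top_k: must be >= 1")

  chk(!is.null(cfg$output_dir), "output_dir: required")
  dedup <- isTRUE(cfg$deduplicate_cases)

  if (length(errs)) {
    stop(paste0("invalid study config:\n  ", paste(errs, collapse = "\n  ")),
         call. = FALSE)
  }
  structure(list(
    inputs = inp, dialect = dialect, termset = termset_path,
    synonym_map = synonym_path, filter = filter, criteria = criteria,
    ranking = list(by = by, top_k = as.integer(top_k)),
    output_dir = cfg$output_dir, deduplicate_cases = dedup,
    seed = as.integer(cfg$seed %||% 1L)
  ), class = "study_config")
}

#' Run a full disproportionality study
#'
#' Orchestrates ingest, drug-name normalization, case selection, descriptive
#' summaries, signal statistics and ranking from one validated config, and
#' writes all artifacts (CSV tables, reject logs, a JSON manifest of counts
#' at every stage) into the output directory. Any stage error aborts the
#' run, removes partial outputs, and names the failing stage. With zero
#' cases after filtering the run exits gracefully with status `"no cases"`
#' and no signal table.
#'
#' @param config A `study_config` from [validate_config()] (or a path/list,
#'   validated on the fly).
#' @return The manifest, invisibly: a list of stage counts, the status, and
#'   the artifact paths.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path, na = "")
    written <<- c(written, path)
    path
  }
  stage <- "ingest"
  manifest <- NULL
  tryCatch({
    rs <- read_reports(config$inputs$demo, config$inputs$drug,
                       config$inputs$reac, config$inputs$outc, config$dialect)
    counts <- list(reports_read = n_reports(rs) + nrow(rs$quarantine),
                   reports_linked = n_reports(rs),
                   quarantined = nrow(rs$quarantine))
    if (nrow(rs$quarantine)) emit(rs$quarantine, "quarantine_log.csv")
    if (config$deduplicate_cases) {
      stage <- "deduplicate"
      rs <- deduplicate_cases(rs)
      counts$after_dedup <- n_reports(rs)
    }
    stage <- "normalize"
    syn <- load_synonym_map(config$synonym_map)
    norm <- normalize_drugs(rs, syn)
    rs <- norm$report_set
    if (nrow(norm$dropped)) emit(norm$dropped, "dropped_log.csv")
    counts$after_normalize <- n_reports(rs)

    stage <- "select"
    ts <- load_termset(config$termset)
    cs <- select_cases(rs, ts, config$filter)
    counts$universe <- length(cs$universe_ids)
    counts$cases <- length(cs$case_ids)

    stage <- "describe"
    if (length(cs$case_ids)) {
      for (v in c("sex", "age_band", "reporter", "country", "outcomes")) {
        emit(tabulate_cases(cs, v), sprintf("table_%s.csv", v))
      }
      emit(yearly_counts(cs), "yearly_counts.csv")
      tto <- time_to_onset(rs, cs$case_ids)
      emit(tto, "time_to_onset.csv")
    }

    stage <- "signal"
    status <- "ok"
    if (!length(cs$case_ids)) {
      status <- "no cases"
      counts$drugs_analyzed <- 0L
      counts$signals <- 0L
    } else {
      st <- signal_table(cs, config$criteria)
      ranked <- rank_signals(st, by = config$ranking$by,
                             top_k = config$ranking$top_k)
      emit(ranked, "signal_table.csv")
      counts$drugs_analyzed <- nrow(st)
      counts$signals <- sum(st$signal, na.rm = TRUE)
    }

    manifest <- list(status = status, counts = counts,
                     artifacts = as.list(written))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("study aborted at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}
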