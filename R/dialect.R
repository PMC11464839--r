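#' Delimited-file dialects for report tables
#'
#' A dialect bundles the low-level conventions of a set of delimited report
#' tables: field delimiter, date format, and file-name suffix. Two presets are
#' provided: [faers_dialect()] mirrors the raw quarterly-file convention
#' (`$`-delimited, `YYYYMMDD` dates), [csv_dialect()] is plain comma-delimited
#' with ISO-8601 dates.
#'
#' @param delimiter Single-character field separator.
#' @param date_format Either `"ymd_compact"` (`YYYYMMDD`) or `"iso"`
#'   (`YYYY-MM-DD`).
#' @param extension File extension (without dot) used by [write_reports()].
#'
#' @return A `pv_dialect` object.
#' @export
#' @examples
#' report_dialect(delimiter = ";", date_format = "iso")
report_dialect <- function(delimiter = ",", date_format = c("iso", "ymd_compact"),
                           extension = "txt") {
  date_format <- match.arg(date_format)
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L)
  structure(
    list(delimiter = delimiter, date_format = date_format, extension = extension),
    class = "pv_dialect"
  )
}

#' @rdname report_dialect
#' @export
faers_dialect <- function() report_dialect("$", "ymd_compact", extension = "txt")

#' @rdname report_dialect
#' @export
csv_dialect <- function() report_dialect(",", "iso", extension = "csv")

#' @export
print.pv_dialect <- function(x, ...) {
  cat(sprintf("<pv_dialect> delimiter=%s dates=%s ext=.%s\n",
              encodeString(x$delimiter, quote = "'"), x$date_format, x$extension))
  invisible(x)
}

format_dialect_date <- function(x, dialect) {
  fmt <- if (dialect$date_format == "ymd_compact") "%Y%m%d" else "%Y-%m-%d"
  ifelse(is.na(x), NA_character_, format(x, fmt))
}

parse_dialect_date <- function(x, dialect) {
  fmt <- if (dialect$date_format == "ymd_compact") "%Y%m%d" else "%Y-%m-%d"
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & x != ""
  out[ok] <- as.Date(as.character(x[ok]), format = fmt)
  out
}
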