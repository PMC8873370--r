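#' Line-listing CSV schema
#'
#' Column names of the canonical line-listing layout used throughout the
#' package: one row per (report, reaction) pair, so a report mentioning
#' several preferred terms spans several rows sharing a `report_id`.
#'
#' @return Character vector of mandatory column names.
#' @export
linelisting_columns <- function() {
  c("report_id", "drug", "reaction_pt", "soc", "age_group", "sex", "route",
    "year", "serious", "outcome", "concomitant")
}

#' Read a spontaneous-report line listing from CSV
#'
#' Reads a one-row-per-(report, reaction) CSV export. Real dashboard exports
#' use varying headers; `col_map` renames them onto the canonical schema
#' (`c(canonical = "export name")`). Unknown columns are preserved. Rows with
#' an unparseable `year` are collected as row errors (with their line
#' numbers) rather than read; under `strict = TRUE` they abort the read.
#'
#' @param path Path to a CSV file whose header covers [linelisting_columns()]
#'   after applying `col_map`.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @param strict If `TRUE`, malformed rows raise an error instead of being
#'   dropped.
#' @return A data frame of reports; malformed rows, if any, are attached as
#'   attribute `"row_errors"` (a data frame with `line` and `message`).
#' @export
read_line_listing <- function(path, col_map = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (is.na(j)) {
        stop(sprintf("mapped column '%s' (for '%s') not found in file",
                     col_map[[canon]], canon), call. = FALSE)
      }
      names(raw)[j] <- canon
    }
  }
  missing <- setdiff(linelisting_columns(), names(raw))
  if (length(missing)) {
    stop("line listing is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  year <- suppressWarnings(as.integer(raw$year))
  bad <- which(is.na(year))
  errors <- data.frame(line = bad + 1L,  # +1 for the header line
                       message = rep("unparseable year", length(bad)))
  if (length(bad) && strict) {
    stop(sprintf("%d malformed row(s); first at file line %d (unparseable year)",
                 length(bad), errors$line[1]), call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- raw[keep, , drop = FALSE]
  out$year <- year[keep]
  out$serious <- norm_label(out$serious) %in% c("true", "t", "1", "yes")
  if (any(!nzchar(out$report_id))) {
    stop("empty report_id encountered", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "row_errors") <- errors
  out
}

#' Write a line listing to CSV
#'
#' Writes the canonical CSV layout; internal bookkeeping columns (names
#' starting with a dot, e.g. the generator's `.duplicate_of`) are dropped.
#'
#' @param reports Line-listing data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(reports, path) {
  keep <- !startsWith(names(reports), ".")
  utils::write.csv(reports[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' De-duplicate a line listing with a deterministic key
#'
#' Spontaneous-report databases accumulate duplicated submissions of one
#' clinical event. Manual curation does not reproduce, so duplicates are
#' removed mechanically: rows sharing the duplicate key are collapsed to the
#' first occurrence in input order. The default key — drug, preferred term,
#' age group, sex, route, year, seriousness — treats two rows describing an
#' identical (drug, reaction, demographics) combination as one case; text
#' fields are compared case-insensitively after trimming. The operation is
#' idempotent.
#'
#' @param reports Line-listing data frame.
#' @param key Character vector of column names forming the duplicate key.
#' @return The retained rows, with attribute `"n_removed"` (number of rows
#'   dropped) and `"n_raw"` (input row count).
#' @export
deduplicate <- function(reports,
                        key = c("drug", "reaction_pt", "age_group", "sex",
                                "route", "year", "serious")) {
  missing <- setdiff(key, names(reports))
  if (length(missing)) {
    stop("duplicate key column(s) not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(reports) == 0) {
    out <- reports
  } else {
    keystr <- do.call(paste, c(lapply(reports[key], function(col) {
      if (is.character(col) || is.factor(col)) norm_label(col) else col
    }), sep = "\r"))
    out <- reports[!duplicated(keystr), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_raw") <- nrow(reports)
  attr(out, "n_removed") <- nrow(reports) - nrow(out)
  out
}

#' Filter specification for building an analysis set
#'
#' Selection criteria applied to a line listing: demographic strata, route,
#' an inclusive year window, and optional SOC/PT restrictions. `NULL` means
#' "no restriction". The canonical study stratum of the anti-HER2 analyses is
#' females aged 18–64, years 2015–2020.
#'
#' @param age_groups,sexes,routes,socs,pts Optional character vectors of
#'   admissible values (matched case-insensitively after trimming).
#' @param years Optional length-2 numeric vector `c(first, last)`, both
#'   inclusive.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(age_groups = NULL, sexes = NULL, routes = NULL,
                        years = NULL, socs = NULL, pts = NULL) {
  if (!is.null(years)) {
    if (length(years) != 2 || any(!is.finite(years)) || years[1] > years[2]) {
      stop("'years' must be c(first, last) with first <= last", call. = FALSE)
    }
    years <- as.integer(years)
  }
  structure(list(age_groups = age_groups, sexes = sexes, routes = routes,
                 years = years, socs = socs, pts = pts),
            class = "filter_spec")
}

#' Filter a line listing into an analysis set
#'
#' Applies a [filter_spec()] and wraps the retained rows together with
#' provenance counts (raw, de-duplicated, filtered). If `reports` carries the
#' attributes set by [deduplicate()], those feed the provenance; otherwise
#' the input count is used for both upstream steps. A spec that removes every
#' row yields an empty analysis set with a warning, not an error.
#'
#' @param reports Line-listing data frame (typically after [deduplicate()]).
#' @param spec A [filter_spec()].
#' @return An object of class `analysis_set`: list with elements `reports`
#'   and `provenance` (data frame of step counts, non-increasing).
#' @export
filter_reports <- function(reports, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(reports))
  match_in <- function(col, allowed) norm_label(col) %in% norm_label(allowed)
  if (!is.null(spec$age_groups)) keep <- keep & match_in(reports$age_group, spec$age_groups)
  if (!is.null(spec$sexes)) keep <- keep & match_in(reports$sex, spec$sexes)
  if (!is.null(spec$routes)) keep <- keep & match_in(reports$route, spec$routes)
  if (!is.null(spec$socs)) keep <- keep & match_in(reports$soc, spec$socs)
  if (!is.null(spec$pts)) keep <- keep & match_in(reports$reaction_pt, spec$pts)
  if (!is.null(spec$years)) {
    keep <- keep & !is.na(reports$year) &
      reports$year >= spec$years[1] & reports$year <= spec$years[2]
  }
  retained <- reports[keep, , drop = FALSE]
  rownames(retained) <- NULL
  if (nrow(reports) > 0 && nrow(retained) == 0) {
    warning("filter removed every report; analysis set is empty", call. = FALSE)
  }
  n_raw <- attr(reports, "n_raw") %||% nrow(reports)
  n_dedup <- nrow(reports)
  structure(
    list(reports = retained,
         spec = spec,
         provenance = data.frame(step = c("raw", "deduplicated", "filtered"),
                                 n = c(n_raw, n_dedup, nrow(retained)))),
    class = "analysis_set"
  )
}

#' Wrap a line listing as an analysis set without filtering
#'
#' @param reports Line-listing data frame.
#' @return An `analysis_set` whose provenance records no removals beyond any
#'   recorded de-duplication.
#' @export
as_analysis_set <- function(reports) filter_reports(reports, filter_spec())

#' @export
print.analysis_set <- function(x, ...) {
  cat("Analysis set of", nrow(x$reports), "(report, reaction) rows\n")
  cat("  provenance:",
      paste(sprintf("%s=%d", x$provenance$step, x$provenance$n), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Tally an analysis set by a key column
#'
#' Counts (report, reaction) rows per value of the key, the counting unit of
#' dashboard tallies: each row carries one preferred term and one SOC, so
#' counts always sum to the number of rows.
#'
#' @param x An `analysis_set` or a line-listing data frame.
#' @param key One of `"reaction_pt"`, `"soc"`, `"drug"`, `"year"`.
#' @return Named integer vector of counts.
#' @export
count_by <- function(x, key = c("reaction_pt", "soc", "drug", "year")) {
  key <- match.arg(key)
  reports <- if (inherits(x, "analysis_set")) x$reports else x
  if (nrow(reports) == 0) return(stats::setNames(integer(), character()))
  tab <- table(reports[[key]])
  stats::setNames(as.integer(tab), names(tab))
}
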