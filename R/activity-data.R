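# Minute- and day-level activity records: CSV IO, validation, aggregation,
# missing-data handling. Storage is always seconds (sensor native); conversion
# to minutes happens only at rule-evaluation boundaries.

MOX_COLUMNS <- c("Date", "Time", "UploadStatus", "IMA", "WeightBearing",
                 "Sedentary", "Standing", "LPA", "MPA", "VPA", "Steps")

MINUTE_FIELDS <- c("date", "time", "upload_status", "ima", "weight_bearing_s",
                   "sedentary_s", "standing_s", "lpa_s", "mpa_s", "vpa_s",
                   "steps")

SECOND_FIELDS <- c("weight_bearing_s", "sedentary_s", "standing_s",
                   "lpa_s", "mpa_s", "vpa_s")

#' Read a minute-level activity CSV (MOX2-5 style)
#'
#' Parses a CSV whose header carries the sensor's native columns
#' (`Date, Time, UploadStatus, IMA, WeightBearing, Sedentary, Standing, LPA,
#' MPA, VPA, Steps`; matching is case-insensitive) into minute records in
#' chronological order. Each minute's six second-budget fields must sum to
#' 60 s; rows violating the budget are reported by file line number as a
#' warning, rows with non-numeric values in numeric fields raise an error
#' naming the lines, and a missing mandatory column raises an error naming
#' the column.
#'
#' @param path path to the CSV file.
#' @return a data.frame of minute records with columns `date` (Date), `time`
#'   (character `"HH:MM:SS"`), `upload_status`, `ima`, `weight_bearing_s`,
#'   `sedentary_s`, `standing_s`, `lpa_s`, `mpa_s`, `vpa_s`, `steps`.
#' @seealso [write_mox_csv()], [aggregate_to_daily()]
#' @export
read_mox_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  hdr <- tolower(trimws(names(raw)))
  want <- tolower(MOX_COLUMNS)
  miss <- setdiff(want, hdr)
  if (length(miss)) {
    stop("missing mandatory column(s): ",
         paste(MOX_COLUMNS[match(miss, want)], collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[match(want, hdr)]
  names(raw) <- MINUTE_FIELDS

  num_fields <- c("ima", SECOND_FIELDS, "steps")
  bad_lines <- integer(0)
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    bad_lines <- union(bad_lines, which(is.na(v) & !is.na(raw[[f]])))
    raw[[f]] <- v
  }
  if (length(bad_lines)) {
    stop("non-numeric value(s) in numeric field(s) at file line(s): ",
         paste(sort(bad_lines) + 1L, collapse = ", "), call. = FALSE)
  }
  raw$date <- as.Date(raw$date)
  ord <- order(raw$date, raw$time)
  rec <- raw[ord, , drop = FALSE]
  rownames(rec) <- NULL
  validate_minute_records(rec, line_offset = 1L, order_map = ord)
  rec
}

#' Write minute records to CSV with the sensor's native header
#'
#' Inverse of [read_mox_csv()]; a write/read round trip reproduces the
#' records field for field.
#'
#' @param records minute-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mox_csv <- function(records, path) {
  out <- records[MINUTE_FIELDS]
  names(out) <- MOX_COLUMNS
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate minute records
#'
#' Checks field ranges (second fields in \[0, 60\], IMA and steps
#' non-negative), flags upload-status values outside `H`/`L`, and warns with
#' row numbers when a minute's second budget does not sum to 60 s.
#'
#' @param records minute-record data.frame.
#' @param line_offset added to row indices when reporting (1 for a CSV with a
#'   header line).
#' @param order_map optional permutation mapping sorted rows back to original
#'   file rows.
#' @return `records`, invisibly.
#' @export
validate_minute_records <- function(records, line_offset = 0L,
                                    order_map = NULL) {
  secs <- as.matrix(records[SECOND_FIELDS])
  if (any(secs < 0 | secs > 60)) {
    stop("second fields must lie in [0, 60]", call. = FALSE)
  }
  check_nonneg(records$ima, "ima")
  check_nonneg(records$steps, "steps")
  bad <- which(abs(rowSums(secs) - 60) > 1e-9)
  if (length(bad)) {
    rows <- if (is.null(order_map)) bad else order_map[bad]
    warning("second-budget violation (sum != 60 s) at row(s): ",
            paste(sort(rows) + line_offset, collapse = ", "), call. = FALSE)
  }
  odd <- !records$upload_status %in% c("H", "L")
  if (any(odd)) {
    warning(sum(odd), " record(s) with UploadStatus outside {H, L} ",
            "(preserved as-is)", call. = FALSE)
  }
  invisible(records)
}

#' Aggregate minute records to daily totals
#'
#' Sums steps and all activity-second fields per calendar date
#' (midnight-to-midnight in the record's local timestamps). Duplicate minutes
#' are summed. Empty input yields an empty daily frame.
#'
#' @param records minute-record data.frame (any participant column is carried
#'   through as a grouping key).
#' @return daily data.frame with columns (`participant`,) `date`, `steps`,
#'   `sedentary_s`, `lpa_s`, `mpa_s`, `vpa_s`.
#' @export
aggregate_to_daily <- function(records) {
  cols <- c("steps", "sedentary_s", "lpa_s", "mpa_s", "vpa_s")
  keys <- intersect(c("participant", "date"), names(records))
  if (nrow(records) == 0) {
    out <- records[0, c(keys, cols), drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  agg <- aggregate(records[cols], by = records[keys], FUN = sum)
  agg <- agg[do.call(order, agg[keys]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Read / write a daily activity CSV
#'
#' Daily CSVs carry columns `date, steps, sedentary_s, lpa_s, mpa_s, vpa_s`
#' and optionally `sleep_minutes`; dates are ISO-8601.
#'
#' @param path file path.
#' @return `read_daily_csv`: a daily data.frame sorted by date.
#' @export
read_daily_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "steps", "sedentary_s", "lpa_s", "mpa_s", "vpa_s")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$date <- as.Date(d$date)
  if (anyDuplicated(d[intersect(c("participant", "date"), names(d))])) {
    stop("at most one record per (participant, date) is allowed",
         call. = FALSE)
  }
  d <- d[order(d$date), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @param daily daily data.frame.
#' @rdname read_daily_csv
#' @export
write_daily_csv <- function(daily, path) {
  write.csv(daily, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill gaps in an ordered daily series
#'
#' Leading missing values are filled backward from the first observation; all
#' other gaps are filled forward from the most recent observation. When
#' `dates` is supplied the series is first expanded to the full calendar span
#' (one value per day), so the output length equals the span.
#'
#' @param x numeric vector, possibly with `NA` gaps.
#' @param dates optional `Date` vector parallel to `x`; missing calendar days
#'   become gaps to fill.
#' @return a gap-free numeric vector (with a `dates` attribute when `dates`
#'   was supplied).
#' @examples
#' fill_missing(c(5, NA, NA, 8))
#' fill_missing(c(NA, 4, 6))
#' @export
fill_missing <- function(x, dates = NULL) {
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    check_length(dates, length(x), "dates")
    span <- seq(min(dates), max(dates), by = "day")
    full <- rep(NA_real_, length(span))
    full[match(dates, span)] <- x
    x <- full
  }
  if (all(is.na(x))) {
    stop("cannot fill an all-missing series (no anchor value)", call. = FALSE)
  }
  out <- zoo::na.locf(zoo::na.locf(x, na.rm = FALSE), fromLast = TRUE)
  if (!is.null(dates)) attr(out, "dates") <- span
  out
}
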