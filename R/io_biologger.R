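# Reading and writing biologger streams and pipeline tables.
#
# CSV dialect used throughout: comma-separated, header row required, UTF-8,
# missing values written as empty cells. Timestamps are treated as raw UTC
# throughout the package; no timezone arithmetic happens anywhere.

.parse_epoch <- function(x, what = "timestamp") {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  tt <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(tt)) stop("unparseable ", what, " values", call. = FALSE)
  as.numeric(tt)
}

#' Read a per-bird GPS log
#'
#' Reads a CSV of GPS fixes (columns `timestamp`, `lon`, `lat`; nominal 5 Hz),
#' attaches bird/loft/flight identifiers, sorts by time and collapses
#' duplicate timestamps to their first occurrence.
#'
#' @param path path to a CSV file with columns `timestamp`, `lon`, `lat`.
#'   Timestamps may be numeric seconds since epoch or ISO-8601 UTC strings.
#' @param bird_id,loft_id identifiers attached to every fix.
#' @param flight_date calendar date of the flight (`Date` or `"YYYY-MM-DD"`).
#' @return A data.frame of fixes (`bird_id`, `loft_id`, `flight_date`, `t`,
#'   `lon`, `lat`) sorted by `t`, with the number of dropped duplicate rows in
#'   attribute `dropped`.
#' @export
read_gps <- function(path, bird_id, loft_id, flight_date) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("GPS file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty GPS stream: ", path, call. = FALSE)
  t <- .parse_epoch(df$timestamp)
  lon <- as.numeric(df$lon); lat <- as.numeric(df$lat)
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(!is.finite(lon)) || any(lon < -180 | lon > 180))
    stop("longitude out of [-180, 180]", call. = FALSE)
  o <- order(t)
  t <- t[o]; lon <- lon[o]; lat <- lat[o]
  keep <- !duplicated(t)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " duplicate GPS timestamp(s) dropped (first kept)")
  out <- data.frame(bird_id = as.character(bird_id),
                    loft_id = as.character(loft_id),
                    flight_date = as.character(as.Date(flight_date)),
                    t = t[keep], lon = lon[keep], lat = lat[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Read a per-bird z-axis accelerometry log
#'
#' Reads a CSV of vertical acceleration samples (columns `timestamp`, `z`;
#' nominal 100 Hz), sorts by time, and attaches a sampling-rate estimate
#' (reciprocal median inter-sample gap) as attribute `sample_rate_hz`.
#'
#' @param path path to a CSV file with columns `timestamp`, `z` (g units).
#' @param bird_id identifier attached to every sample.
#' @param flight_date calendar date of the flight.
#' @return A data.frame (`bird_id`, `flight_date`, `t`, `z`) sorted by `t`.
#' @export
read_accel <- function(path, bird_id, flight_date) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("accelerometry file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty accelerometry stream: ", path, call. = FALSE)
  suppressWarnings(z <- as.numeric(df$z))
  if (anyNA(z)) stop("non-numeric z values in ", path, call. = FALSE)
  t <- .parse_epoch(df$timestamp)
  if (is.unsorted(t)) {
    warning("accelerometry timestamps out of order; sorting", call. = FALSE)
    o <- order(t); t <- t[o]; z <- z[o]
  }
  out <- data.frame(bird_id = as.character(bird_id),
                    flight_date = as.character(as.Date(flight_date)),
                    t = t, z = z, stringsAsFactors = FALSE)
  gaps <- diff(t)
  attr(out, "sample_rate_hz") <-
    if (length(gaps)) 1 / median(gaps) else NA_real_
  out
}

#' Write a track-record table to CSV
#'
#' One row per record, stable column order, an ISO-8601 `timestamp` column
#' derived from the numeric second `t`, and empty cells (never the string
#' `"NA"`/`"NaN"`) for missing values. [read_track_table()] inverts it.
#'
#' @param records a data.frame of per-second track records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  if ("t" %in% names(df) && !("timestamp" %in% names(df))) {
    iso <- format(as.POSIXct(df$t, origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%SZ")
    df <- cbind(timestamp = iso, df, stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a track-record table written by [write_track_table()]
#'
#' @param path CSV path.
#' @return data.frame with the original columns (the derived `timestamp`
#'   column is dropped when a numeric `t` is present).
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (all(c("timestamp", "t") %in% names(df)))
    df$timestamp <- NULL
  df
}
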