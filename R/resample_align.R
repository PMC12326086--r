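# Reduction of all streams to aligned per-second records, stream merging,
# and subsampling against temporal autocorrelation.

#' Reduce a timestamped stream to per-second medians
#'
#' Buckets values by `floor(t)` and takes the median per bucket,
#' component-wise for several value columns. Empty buckets are absent.
#'
#' @param stream data.frame with a time column and one or more value columns.
#' @param value_cols names of the value columns.
#' @param t_col name of the time column (default `"t"`).
#' @return data.frame with whole-second `t` and the per-second medians.
#' @export
to_per_second <- function(stream, value_cols, t_col = "t") {
  if (!nrow(stream)) {
    out <- c(list(t = numeric(0)),
             stats::setNames(rep(list(numeric(0)), length(value_cols)),
                             value_cols))
    return(as.data.frame(out))
  }
  sec <- floor(stream[[t_col]])
  out <- data.frame(t = sort(unique(sec)))
  for (vc in value_cols) {
    med <- tapply(stream[[vc]], sec, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) median(v) else NA_real_
    })
    out[[vc]] <- as.numeric(med[as.character(out$t)])
  }
  out
}

#' Merge per-second streams into track records
#'
#' Inner-joins on position-bearing records: a record exists only where a GPS
#' second exists; flap-frequency and flock-geometry fields are missing where
#' those streams have no matching second. Counts of unmatched seconds are
#' reported via `message()`.
#'
#' @param gps_s data.frame keyed by (`bird_id`, `flight_date`, `t`) with
#'   position/speed columns; the spine of the result.
#' @param flap_s per-second flap frequencies (same key), or `NULL`.
#' @param habitat_s per-second habitat categories (same key), or `NULL`.
#' @param flock_s per-second flock-geometry rows (same key), or `NULL`.
#' @return data.frame of merged track records, one row per key.
#' @export
merge_streams <- function(gps_s, flap_s = NULL, habitat_s = NULL,
                          flock_s = NULL) {
  key <- c("bird_id", "flight_date", "t")
  stopifnot(all(key %in% names(gps_s)))
  if (anyDuplicated(gps_s[key]))
    stop("conflicting duplicate (bird, flight, second) keys in GPS stream",
         call. = FALSE)
  out <- gps_s
  join <- function(base, extra, label) {
    if (is.null(extra) || !nrow(extra)) return(base)
    if (anyDuplicated(extra[key]))
      stop("conflicting duplicate keys in ", label, " stream", call. = FALSE)
    merged <- merge(base, extra, by = key, all.x = TRUE, sort = FALSE)
    unmatched <- nrow(extra) - sum(interaction(extra[key]) %in%
                                     interaction(base[key]))
    if (unmatched > 0L)
      message(unmatched, " ", label,
              " second(s) had no GPS second and were dropped")
    merged
  }
  out <- join(out, flap_s, "flap")
  out <- join(out, habitat_s, "habitat")
  out <- join(out, flock_s, "flock")
  if (!nrow(out)) warning("merge produced zero records", call. = FALSE)
  out[order(out$bird_id, out$flight_date, out$t), , drop = FALSE]
}

#' Subsample per-second records against autocorrelation
#'
#' Retains every `rate`-th second per bird and flight. The retained-second
#' grid is anchored at the first second of each flight and shared across the
#' flock's birds, so retained timestamps match between flock members.
#'
#' @param records track records with `flock_id`, `flight_date`, `bird_id`,
#'   `t` (whole seconds), sorted by `t` within bird-flight.
#' @param rate keep one record in `rate` (default 15).
#' @return the retained records.
#' @export
subsample_records <- function(records, rate = 15) {
  stopifnot(rate >= 1)
  if (!nrow(records)) return(records)
  key <- interaction(records$flock_id, records$flight_date, drop = TRUE)
  anchor <- ave(records$t, key, FUN = min)
  keep <- ((records$t - anchor) %% rate) == 0
  records[keep, , drop = FALSE]
}

#' Sample autocorrelation with pairwise NA handling
#'
#' Standard sample autocorrelation at lags `1..max_lag`; pairs with a
#' missing member are dropped lag-wise.
#'
#' @param series numeric vector.
#' @param max_lag largest lag.
#' @return numeric vector of lag-1..max_lag correlations.
#' @export
autocorrelation <- function(series, max_lag) {
  n <- length(series)
  if (n <= max_lag + 2) stop("series too short for max_lag", call. = FALSE)
  if (sd(series, na.rm = TRUE) == 0 || all(is.na(series)))
    stop("zero-variance series: autocorrelation undefined", call. = FALSE)
  vapply(seq_len(max_lag), function(k) {
    cor(series[seq_len(n - k)], series[(k + 1):n],
        use = "pairwise.complete.obs")
  }, numeric(1))
}
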