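# Flap (wingbeat) frequency from dorsal z-axis accelerometry.
#
# Stages: (1) remove gravity and slow drift with a subtracted centered
# running mean; (2) detect wingbeat peaks on the detrended signal and turn
# inter-peak intervals into instantaneous frequencies, summarised over
# consecutive 15-sample windows; (3) zero-phase Butterworth low-pass on the
# window-rate frequency series; (4) aggregate to per-second medians.
#
# The 1 s detrend window is long against a ~0.14 s wingbeat period (the
# running mean barely touches the signal) and short against drift. Peak
# positions are refined by parabolic interpolation so the 100 Hz sampling
# grid does not quantise the inter-peak intervals.

.running_mean <- function(x, k) {
  # centered running mean with shrunken windows at the edges
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.running_sd <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1L
  mu <- (cs[hi + 1L] - cs[lo]) / m
  v <- pmax((cs2[hi + 1L] - cs2[lo]) / m - mu^2, 0)
  sqrt(v)
}

#' Remove gravity and drift from a z-axis acceleration series
#'
#' Subtracts a centered running mean of width `window_s` seconds, removing
#' the ~1 g gravity offset and slow drift while leaving the wingbeat
#' oscillation essentially untouched. Edges use shrunken windows, so length
#' is preserved.
#'
#' @param z numeric acceleration series (g).
#' @param sample_rate sampling rate in Hz.
#' @param window_s running-mean window in seconds (default 1).
#' @return detrended numeric series, same length as `z`.
#' @export
detrend_z <- function(z, sample_rate, window_s = 1) {
  stopifnot(window_s > 0, sample_rate > 0)
  k <- max(3L, round(window_s * sample_rate))
  if (k > length(z))
    stop("detrend window (", k, " samples) longer than series (",
         length(z), ")", call. = FALSE)
  z - .running_mean(z, k)
}

#' Estimate flap frequency over fixed sample windows
#'
#' Detects wingbeat peaks on a detrended z-axis series (local maxima whose
#' height exceeds `prominence_factor` times the rolling signal standard
#' deviation, with sub-sample parabolic refinement), converts inter-peak
#' intervals to instantaneous frequencies, and assigns each consecutive
#' `window_len`-sample window the mean instantaneous frequency of the
#' intervals overlapping it. Windows overlapped by no interval are `NA`.
#'
#' @param z_detrended detrended acceleration series (see [detrend_z()]).
#' @param sample_rate sampling rate in Hz.
#' @param window_len samples per estimation window (default 15).
#' @param prominence_factor peak threshold as a multiple of the 1 s rolling
#'   standard deviation (default 0.3).
#' @param t0 time of the first sample (seconds; default 0) used for the
#'   window centre timestamps.
#' @return a `flap_series`: data.frame with `t` (window centre, s) and `f`
#'   (Hz), with `sample_rate`, `window_len` and `window_rate` attributes.
#'   A flat signal yields an all-`NA` series flagged via attribute `flat`.
#' @export
estimate_flap_frequency <- function(z_detrended, sample_rate,
                                    window_len = 15,
                                    prominence_factor = 0.3, t0 = 0) {
  stopifnot(window_len >= 2, sample_rate > 0)
  n <- length(z_detrended)
  n_win <- n %/% window_len
  if (n_win < 1L) stop("series shorter than one window", call. = FALSE)
  wdt <- window_len / sample_rate
  out <- data.frame(t = t0 + (seq_len(n_win) - 0.5) * wdt,
                    f = rep(NA_real_, n_win))
  attr(out, "sample_rate") <- sample_rate
  attr(out, "window_len") <- window_len
  attr(out, "window_rate") <- sample_rate / window_len
  rs <- .running_sd(z_detrended, max(3L, round(sample_rate)))
  if (all(rs < 1e-12)) {               # flat signal: nothing to detect
    attr(out, "flat") <- TRUE
    class(out) <- c("flap_series", class(out))
    return(out)
  }
  # light zero-phase pre-smoothing so sensor noise does not split a wingbeat
  # peak in two: ~0.05 s moving average barely attenuates the wingbeat band
  k_sm <- max(3L, round(sample_rate / 20))
  zs <- .running_mean(z_detrended, k_sm)
  i <- 2:(n - 1L)
  is_peak <- zs[i] > zs[i - 1L] & zs[i] >= zs[i + 1L] &
             zs[i] > prominence_factor * rs[i]
  pk <- i[is_peak]
  # refractory pruning: drop the lower of any peak pair closer than the
  # shortest physical wingbeat period the estimator entertains (20 Hz)
  if (length(pk) > 1L) {
    min_sep <- max(3L, round(sample_rate / 20))
    repeat {
      gaps <- diff(pk)
      close_ <- which(gaps < min_sep)
      if (!length(close_)) break
      j <- close_[1L]
      drop_idx <- if (zs[pk[j]] < zs[pk[j + 1L]]) j else j + 1L
      pk <- pk[-drop_idx]
    }
  }
  if (length(pk) >= 2L) {
    # parabolic sub-sample refinement of each peak location
    y1 <- zs[pk - 1L]; y2 <- zs[pk]; y3 <- zs[pk + 1L]
    den <- y1 - 2 * y2 + y3
    shift <- ifelse(abs(den) > 1e-12, 0.5 * (y1 - y3) / den, 0)
    shift[abs(shift) > 0.5] <- 0
    tp <- (pk - 1L + shift) / sample_rate        # seconds from series start
    iv_s <- tp[-length(tp)]
    iv_e <- tp[-1L]
    f_inst <- 1 / (iv_e - iv_s)
    ok <- is.finite(f_inst) & f_inst > 0 & f_inst <= sample_rate / 2
    iv_s <- iv_s[ok]; iv_e <- iv_e[ok]; f_inst <- f_inst[ok]
    if (length(f_inst)) {
      j1 <- pmax(0L, pmin(n_win - 1L, floor(iv_s / wdt)))
      j2 <- pmax(0L, pmin(n_win - 1L, floor(iv_e / wdt)))
      span <- j2 - j1 + 1L
      win_idx <- rep(j1, span) + sequence(span) - 1L
      fv <- rep(f_inst, span)
      sums <- tapply(fv, win_idx, sum)
      cnts <- tapply(fv, win_idx, length)
      idx <- as.integer(names(sums)) + 1L
      out$f[idx] <- as.numeric(sums) / as.numeric(cnts)
    }
  }
  attr(out, "flat") <- FALSE
  class(out) <- c("flap_series", class(out))
  out
}

#' Zero-phase Butterworth smoothing of a flap-frequency series
#'
#' Low-pass filters the regularly spaced window-rate frequency series with a
#' forward-backward (zero-phase) Butterworth filter of DC gain 1. Missing
#' runs are linearly interpolated before filtering and re-masked afterwards,
#' so missingness never turns into imputed output.
#'
#' @param f_series a `flap_series` from [estimate_flap_frequency()].
#' @param order filter order (default 2).
#' @param cutoff_hz low-pass cutoff in Hz (default 1); must lie below the
#'   Nyquist frequency of the window rate.
#' @return the series with `f` replaced by its smoothed version.
#' @export
butterworth_smooth <- function(f_series, order = 2, cutoff_hz = 1) {
  rate <- attr(f_series, "window_rate")
  stopifnot(!is.null(rate))
  if (cutoff_hz >= rate / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the window-rate Nyquist (",
         rate / 2, " Hz)", call. = FALSE)
  f <- f_series$f
  na <- is.na(f)
  if (all(na) || sum(!na) < 3 * (order + 1))
    return(f_series)                    # nothing (or too little) to filter
  idx <- seq_along(f)
  filled <- f
  filled[na] <- approx(idx[!na], f[!na], xout = idx[na], rule = 2)$y
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  # mean removal + odd-reflection padding suppress the zero-initial-state
  # edge transient (and make a constant series an exact fixed point)
  mu <- mean(filled)
  xc <- filled - mu
  n <- length(xc)
  npad <- min(n - 1L, max(12L, 3L * ceiling(rate / cutoff_hz)))
  xp <- c(2 * xc[1] - xc[(npad + 1L):2],
          xc,
          2 * xc[n] - xc[(n - 1L):(n - npad)])
  sp <- as.numeric(signal::filtfilt(bf, xp))
  sm <- sp[(npad + 1L):(npad + n)] + mu
  sm[na] <- NA_real_
  f_series$f <- sm
  f_series
}

#' Aggregate a flap-frequency series to per-second medians
#'
#' @param f_series a `flap_series` (columns `t`, `f`).
#' @return data.frame with whole-second `t` and the median `f` of the defined
#'   estimates falling in `[t, t+1)`; seconds with no defined estimate are
#'   absent.
#' @export
aggregate_median_per_second <- function(f_series) {
  keep <- !is.na(f_series$f)
  if (!any(keep))
    return(data.frame(t = numeric(0), flap_frequency = numeric(0)))
  sec <- floor(f_series$t[keep])
  med <- tapply(f_series$f[keep], sec, median)
  data.frame(t = as.numeric(names(med)), flap_frequency = as.numeric(med),
             row.names = NULL)
}

#' Full accelerometry-to-flap-frequency pipeline for one bird-flight
#'
#' Convenience wrapper: detrend, window-wise frequency estimation,
#' Butterworth smoothing, per-second median aggregation.
#'
#' @param accel data.frame with `t` (s) and `z` (g), regularly sampled.
#' @param sample_rate sampling rate in Hz; defaults to the stream's
#'   `sample_rate_hz` attribute or the median-gap estimate.
#' @param detrend_window_s,window_len,butter_order,butter_cutoff_hz,
#'   prominence_factor tuning knobs (see the stage functions).
#' @return data.frame with whole-second `t` and `flap_frequency` (Hz).
#' @export
flap_frequency_per_second <- function(accel, sample_rate = NULL,
                                      detrend_window_s = 1, window_len = 15,
                                      butter_order = 2, butter_cutoff_hz = 1,
                                      prominence_factor = 0.3) {
  rate <- sample_rate %||% attr(accel, "sample_rate_hz") %||%
    (1 / median(diff(accel$t)))
  zd <- detrend_z(accel$z, rate, detrend_window_s)
  fs <- estimate_flap_frequency(zd, rate, window_len, prominence_factor,
                                t0 = accel$t[1])
  fs <- butterworth_smooth(fs, butter_order, butter_cutoff_hz)
  aggregate_median_per_second(fs)
}
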