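# Track geometry: local planar projection, speed, release/home trimming and
# temporal indices.
#
# Projection is a local equirectangular plane about a tangent point (the home
# site by convention): x = (lon - lon0) * cos(lat0) * M, y = (lat - lat0) * M
# with M = 111,320 m/deg. Over a < 10 km corridor the error against a
# great-circle oracle is < 0.1% and the transform is exactly invertible,
# which is why it is preferred here over a UTM dependency.

.M_PER_DEG <- 111320

#' Project GPS fixes onto a local plane
#'
#' @param fixes data.frame with `lon`, `lat` (and any other columns, carried
#'   through; typically the output of [read_gps()]).
#' @param origin numeric `c(lon, lat)` tangent point of the projection.
#' @return the input with `x` (m east) and `y` (m north) columns appended and
#'   the origin stored in attribute `origin`.
#' @export
project_to_plane <- function(fixes, origin) {
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  lon0 <- origin[[1]]; lat0 <- origin[[2]]
  x <- (fixes$lon - lon0) * cos(lat0 * pi / 180) * .M_PER_DEG
  y <- (fixes$lat - lat0) * .M_PER_DEG
  if (any(sqrt(x^2 + y^2) > 5e4))
    stop("fixes beyond 50 km of the projection origin", call. = FALSE)
  out <- fixes
  out$x <- x
  out$y <- y
  attr(out, "origin") <- c(lon = lon0, lat = lat0)
  out
}

#' Invert the local planar projection
#'
#' @param xy data.frame or matrix with `x`, `y` in metres.
#' @param origin numeric `c(lon, lat)`; defaults to the `origin` attribute.
#' @return data.frame with `lon`, `lat`.
#' @export
unproject_from_plane <- function(xy, origin = attr(xy, "origin")) {
  stopifnot(!is.null(origin))
  lon0 <- origin[[1]]; lat0 <- origin[[2]]
  x <- if (is.data.frame(xy)) xy$x else xy[, 1]
  y <- if (is.data.frame(xy)) xy$y else xy[, 2]
  data.frame(lon = lon0 + x / (cos(lat0 * pi / 180) * .M_PER_DEG),
             lat = lat0 + y / .M_PER_DEG)
}

#' Compute per-fix flight speed
#'
#' Speed at fix i is the Euclidean displacement from fix i-1 divided by the
#' time gap. The first fix has no speed. Speeds above `ceiling_ms` are GPS
#' glitches and set missing (count in attribute `implausible`).
#'
#' @param track projected track (`t`, `x`, `y`), strictly increasing `t`.
#' @param ceiling_ms plausibility ceiling in m/s (default 50, well above
#'   racing-pigeon speeds).
#' @return data.frame `t`, `speed` aligned with the track rows.
#' @export
compute_speed <- function(track, ceiling_ms = 50) {
  stopifnot(nrow(track) >= 2)
  dt <- diff(track$t)
  if (any(dt <= 0)) stop("track timestamps not strictly increasing",
                         call. = FALSE)
  sp <- c(NA_real_, sqrt(diff(track$x)^2 + diff(track$y)^2) / dt)
  bad <- !is.na(sp) & sp > ceiling_ms
  sp[bad] <- NA_real_
  out <- data.frame(t = track$t, speed = sp)
  attr(out, "implausible") <- sum(bad)
  out
}

#' Trim fixes near the release and home sites
#'
#' Removes every point lying within `radius_m` (inclusive) of any site, to
#' exclude the atypical ascending/circling/descending flight at the start and
#' end of a homing flight. The retained time span is reported so that other
#' streams (e.g. accelerometry-derived series) can be trimmed to the same
#' window.
#'
#' @param track projected track with `t`, `x`, `y`.
#' @param sites list or matrix of planar site coordinates `(x, y)`.
#' @param radius_m trim radius in metres (default 200).
#' @return the trimmed track, with attribute `span = c(t_start, t_end)` of
#'   the retained fixes (`c(NA, NA)` and a warning when nothing remains).
#' @export
trim_radius <- function(track, sites, radius_m = 200) {
  if (is.list(sites) && !is.data.frame(sites))
    sites <- do.call(rbind, sites)
  sites <- matrix(as.numeric(sites), ncol = 2)
  near <- rep(FALSE, nrow(track))
  for (k in seq_len(nrow(sites))) {
    d <- sqrt((track$x - sites[k, 1])^2 + (track$y - sites[k, 2])^2)
    near <- near | d <= radius_m
  }
  out <- track[!near, , drop = FALSE]
  if (!nrow(out)) {
    warning("all fixes fell within ", radius_m, " m of a site; empty flight",
            call. = FALSE)
    attr(out, "span") <- c(NA_real_, NA_real_)
  } else {
    attr(out, "span") <- c(min(out$t), max(out$t))
  }
  attr(out, "origin") <- attr(track, "origin")
  out
}

#' Attach flight-time and iteration indices
#'
#' `flight_time` counts seconds since the first retained record of the flight
#' (0 at the start, shared across a flock's birds so the clock is common),
#' and `iteration` is the 1-based dense rank of `flight_date` within each
#' flock, ascending by date — a proxy for route familiarity over repeated
#' releases.
#'
#' @param records data.frame with `flock_id`, `flight_date`, `t`.
#' @return the input with `flight_time` and `iteration` columns appended.
#' @export
attach_indices <- function(records) {
  stopifnot(all(c("flock_id", "flight_date", "t") %in% names(records)))
  key <- interaction(records$flock_id, records$flight_date, drop = TRUE)
  t0 <- ave(records$t, key, FUN = min)
  records$flight_time <- records$t - t0
  records$iteration <- NA_integer_
  for (fl in unique(records$flock_id)) {
    sel <- records$flock_id == fl
    dates <- sort(unique(records$flight_date[sel]))
    records$iteration[sel] <- match(records$flight_date[sel], dates)
  }
  records
}
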