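# Synthetic flock-flight campaigns with known ground truth.
#
# The generator emulates the study design the pipeline targets: three flocks
# of 6/10/8 homing pigeons, each released 15 times over a ~9.6 km corridor
# whose ground cover alternates between open, wooded and urban patches.
# Birds follow a correlated random walk with homing bias and flock cohesion;
# ground-cover offsets act on instantaneous speed and flap frequency; GPS is
# emitted at 5 Hz with isotropic noise and dorsal z-axis accelerometry at
# 100 Hz as gravity + flap oscillation + noise + slow drift. The wingbeat
# phase is integrated continuously (a phase accumulator) so frequency
# changes never create discontinuities.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulator configuration
#'
#' Defaults mirror the field design the pipeline analyses: three flocks (L:
#' 6, N: 10, R: 8 birds) flown 15 times along a 9.58 km release-to-home
#' corridor, a mean cruising speed of 17.92 m/s and mean flap frequency of
#' 6.93 Hz, speed offsets of -0.7 m/s over wooded and +0.7 m/s over urban
#' cover, and a -0.1 Hz urban flap-frequency offset.
#'
#' @param n_flights homing flights per flock (default 15).
#' @param birds_per_flock named integer vector, flock id -> bird count.
#' @param release,home site coordinates `c(lon, lat)`.
#' @param corridor_length_m when non-`NULL`, the home site is moved to this
#'   distance from the release along the original axis (scaled-down runs).
#' @param corridor_width_m width of the mapped corridor (default 800).
#' @param base_speed,base_flap habitat-free means (m/s, Hz).
#' @param habitat_speed_offsets,habitat_flap_offsets named vectors
#'   (open/wooded/urban) of additive offsets.
#' @param habitat_spread_multipliers named vector scaling the target
#'   inter-bird spacing by the cover under the flock centroid.
#' @param bird_speed_sd,loft_speed_sd,bird_flap_sd,loft_flap_sd standard
#'   deviations of the random bird/loft intercepts (response units).
#' @param cohesion_strength weight of the cohesion steering term.
#' @param spacing_m target distance to the flock centroid (m).
#' @param speed_match_ms maximum speed adjustment (m/s) a bird makes to hold
#'   station with its flock (birds ahead of the centroid slow down, trailing
#'   birds speed up); zero-mean within the flock, so habitat offsets on the
#'   flock's speed are unaffected. Default 0 (off): station-keeping makes a
#'   bird's realized speed track the flock's, hiding individual speed
#'   intercepts from the mixed models; enable it when a tightly
#'   spacing-controlled spread (e.g. an injected iteration trend) matters
#'   more than individual-speed recovery.
#' @param iteration_spread_trend fractional change of target spacing per
#'   flight iteration (e.g. -0.01 shrinks spread 1\% per flight).
#' @param split_probability_per_min chance per minute that a minority
#'   subgroup splits off.
#' @param split_offset_m lateral displacement a split subgroup aims for
#'   (beyond the 40 m centroid-exclusion distance; default 80).
#' @param split_duration_s how long a split lasts (default 30).
#' @param heading_noise_sd per-step directional noise on the steering
#'   target (default 0.08).
#' @param gps_noise_sd isotropic GPS scatter per fix (m; default 1.5).
#' @param accel_noise_sd white accelerometer noise (g; default 0.1).
#' @param flap_amplitude wingbeat oscillation amplitude (g; default 1).
#' @param drift_amplitude_g,drift_period_s slow accelerometer drift.
#' @param wobble_sd_speed,wobble_sd_flap,wobble_phi AR(1) wobble on the
#'   instantaneous speed and flap frequency (stationary sd, lag-0.2 s phi).
#' @param start_date first release date (all flocks fly on the same dates).
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_flights = 15,
                       birds_per_flock = c(L = 6, N = 10, R = 8),
                       release = c(lon = -0.584229, lat = 51.500122),
                       home = c(lon = -0.572615, lat = 51.415368),
                       corridor_length_m = NULL,
                       corridor_width_m = 800,
                       base_speed = 17.92, base_flap = 6.93,
                       habitat_speed_offsets = c(open = 0, wooded = -0.7,
                                                 urban = 0.7),
                       habitat_flap_offsets = c(open = 0, wooded = 0.03,
                                                urban = -0.1),
                       habitat_spread_multipliers = c(open = 1,
                                                      wooded = 1.25,
                                                      urban = 0.9),
                       bird_speed_sd = 1, loft_speed_sd = 1,
                       bird_flap_sd = 0.2, loft_flap_sd = 0.2,
                       cohesion_strength = 0.3, spacing_m = 5,
                       speed_match_ms = 0,
                       iteration_spread_trend = 0,
                       split_probability_per_min = 0.05,
                       split_offset_m = 80, split_duration_s = 30,
                       heading_noise_sd = 0.08,
                       gps_noise_sd = 1.5, accel_noise_sd = 0.1,
                       flap_amplitude = 1, drift_amplitude_g = 0.05,
                       drift_period_s = 60,
                       wobble_sd_speed = 0.8, wobble_sd_flap = 0.25,
                       wobble_phi = 0.9,
                       start_date = "2022-11-10", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(base_flap + min(habitat_flap_offsets) > 0,
            base_speed + min(habitat_speed_offsets) > 0,
            split_probability_per_min >= 0, split_probability_per_min <= 1,
            all(birds_per_flock >= 1), n_flights >= 1,
            corridor_width_m > 0, gps_noise_sd >= 0, accel_noise_sd >= 0)
  if (!is.null(corridor_length_m)) {
    # move the home site along the original release->home axis
    org <- c(release[["lon"]], release[["lat"]])
    a <- project_to_plane(data.frame(lon = home[["lon"]],
                                     lat = home[["lat"]]), org)
    v <- c(a$x, a$y)
    v <- v / sqrt(sum(v^2)) * corridor_length_m
    ll <- unproject_from_plane(data.frame(x = v[1], y = v[2]), org)
    cfg$home <- c(lon = ll$lon, lat = ll$lat)
  }
  structure(cfg, class = "sim_config")
}

.flock_geometry_frame <- function(config) {
  org <- c(config$release[["lon"]], config$release[["lat"]])
  h <- project_to_plane(data.frame(lon = config$home[["lon"]],
                                   lat = config$home[["lat"]]), org)
  b <- c(h$x, h$y)
  L <- sqrt(sum(b^2))
  u <- b / L
  list(origin_lonlat = org, home_xy = b, L = L, u = u,
       w = c(-u[2], u[1]))
}

#' Generate a deterministic patchwork landscape over the corridor
#'
#' Tiles the release-to-home corridor (plus a 300 m margin at both ends)
#' with non-overlapping rectangular bands perpendicular to the route,
#' assigning open/wooded/urban categories so that a straight
#' release-to-home segment crosses all three and each covers at least 15\%
#' of the corridor. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed seed (default the config's).
#' @return a `habitat_map` with an internal along-axis band table used by
#'   the simulator for fast cover lookup.
#' @export
make_landscape <- function(config, seed = config$seed) {
  geo <- .flock_geometry_frame(config)
  L <- geo$L
  margin <- 300
  classes <- c(open = "Improved Grassland",
               wooded = "Broadleaved, Mixed, and Yew Woodland",
               urban = "Built-up Areas and Gardens")
  bands <- .with_seed(seed, {
    for (attempt in 1:25) {
      s <- -margin
      lens <- numeric(0)
      while (s + sum(lens) < L + margin)
        lens <- c(lens, runif(1, 0.05, 0.10) * (L + 2 * margin))
      cats <- character(length(lens))
      for (i in seq(1, length(lens), by = 3)) {
        idx <- i:min(i + 2, length(lens))
        cats[idx] <- sample(.habitat_levels)[seq_along(idx)]
      }
      starts <- -margin + cumsum(c(0, lens[-length(lens)]))
      ends <- starts + lens
      # coverage of [0, L] proper
      cover <- vapply(.habitat_levels, function(cc) {
        sel <- cats == cc
        sum(pmax(0, pmin(ends[sel], L) - pmax(starts[sel], 0)))
      }, numeric(1)) / L
      if (all(cover >= 0.15)) break
    }
    data.frame(start = starts, end = ends, category = cats,
               stringsAsFactors = FALSE)
  })
  half_w <- config$corridor_width_m / 2
  org <- geo$origin_lonlat
  polys <- lapply(seq_len(nrow(bands)), function(i) {
    s <- bands$start[i]; e <- bands$end[i]
    corners <- rbind(s * geo$u + half_w * geo$w,
                     e * geo$u + half_w * geo$w,
                     e * geo$u - half_w * geo$w,
                     s * geo$u - half_w * geo$w)
    ll <- unproject_from_plane(data.frame(x = corners[, 1],
                                          y = corners[, 2]), org)
    ring <- .close_ring(cbind(ll$lon, ll$lat))
    list(category = bands$category[i],
         source_class = unname(classes[bands$category[i]]),
         rings = list(ring))
  })
  all_xy <- do.call(rbind, unlist(lapply(polys, `[[`, "rings"),
                                  recursive = FALSE))
  map <- structure(
    list(polygons = polys,
         bbox = c(lon_min = min(all_xy[, 1]), lon_max = max(all_xy[, 1]),
                  lat_min = min(all_xy[, 2]), lat_max = max(all_xy[, 2])),
         rejected = character(0)),
    class = "habitat_map")
  attr(map, "bands") <- bands
  attr(map, "frame") <- geo
  map
}

.draw_intercepts <- function(config) {
  .with_seed(config$seed + 7L, {
    flocks <- names(config$birds_per_flock)
    loft_speed <- stats::setNames(rnorm(length(flocks), 0,
                                        config$loft_speed_sd), flocks)
    loft_flap <- stats::setNames(rnorm(length(flocks), 0,
                                       config$loft_flap_sd), flocks)
    birds <- unlist(lapply(flocks, function(fl)
      paste0(fl, seq_len(config$birds_per_flock[[fl]]))))
    bird_speed <- stats::setNames(rnorm(length(birds), 0,
                                        config$bird_speed_sd), birds)
    bird_flap <- stats::setNames(rnorm(length(birds), 0,
                                       config$bird_flap_sd), birds)
    list(loft_speed = loft_speed, loft_flap = loft_flap,
         bird_speed = bird_speed, bird_flap = bird_flap)
  })
}

.habitat_at <- function(bands, s_axis) {
  idx <- findInterval(s_axis, bands$start)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(bands)] <- nrow(bands)
  bands$category[idx]
}

#' Simulate one flock's homing flight
#'
#' Correlated random walk with homing bias and cohesion. Per-habitat offsets
#' act on the instantaneous speed and flap frequency together with
#' bird/loft intercepts and a small AR(1) wobble. Optional splits send a
#' minority subgroup laterally off-axis (beyond the centroid-exclusion
#' distance) for a stated duration before it reintegrates. Returns 5 Hz GPS
#' streams, 100 Hz accelerometry, and the injected ground truth.
#'
#' @param config a [sim_config()].
#' @param landscape a landscape from [make_landscape()].
#' @param flock_id flock name (must exist in the config).
#' @param flight_idx 1-based flight iteration.
#' @param seed seed for this flight's randomness.
#' @param with_accel synthesise accelerometry (default `TRUE`); turning it
#'   off saves time when only GPS-side behaviour is studied.
#' @return list with `gps` (per-bird data.frames: `t`, `lon`, `lat`),
#'   `accel` (per-bird `t`, `z`), and `truth` (per-step speed/flap/habitat
#'   matrices, intercepts, split events, `t0`).
#' @export
simulate_flight <- function(config, landscape, flock_id, flight_idx,
                            seed = config$seed * 1000L + flight_idx,
                            with_accel = TRUE) {
  stopifnot(flock_id %in% names(config$birds_per_flock))
  geo <- attr(landscape, "frame") %||% .flock_geometry_frame(config)
  bands <- attr(landscape, "bands")
  stopifnot(!is.null(bands))
  n <- config$birds_per_flock[[flock_id]]
  ids <- paste0(flock_id, seq_len(n))
  ints <- .draw_intercepts(config)
  dt <- 0.2
  date <- as.Date(config$start_date) + (flight_idx - 1L)
  release_order <- c(L = 0, R = 600, N = 1200)
  t_off <- unname(release_order[flock_id])
  if (is.na(t_off)) t_off <- 0
  t0 <- as.numeric(as.POSIXct(paste(date, "10:00:00"), tz = "UTC")) + t_off
  spacing0 <- config$spacing_m *
    (1 + config$iteration_spread_trend)^(flight_idx - 1L)
  max_steps <- ceiling(3 * geo$L / (config$base_speed * dt)) + 3000L

  .with_seed(seed, {
    # start scattered in a ring about the release
    ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    pos <- cbind(spacing0 * cos(ang), spacing0 * sin(ang))
    dir <- matrix(rep(geo$u, each = n), n, 2)
    wob_sp <- rnorm(n, 0, config$wobble_sd_speed)
    wob_fl <- rnorm(n, 0, config$wobble_sd_flap)
    phi <- config$wobble_phi
    innov_sp <- config$wobble_sd_speed * sqrt(1 - phi^2)
    innov_fl <- config$wobble_sd_flap * sqrt(1 - phi^2)
    loft_sp <- ints$loft_speed[[flock_id]]
    loft_fl <- ints$loft_flap[[flock_id]]
    bird_sp <- ints$bird_speed[ids]
    bird_fl <- ints$bird_flap[ids]
    home <- geo$home_xy

    pos_hist <- vector("list", max_steps)
    spd_hist <- matrix(NA_real_, max_steps, n)
    flp_hist <- matrix(NA_real_, max_steps, n)
    hab_hist <- matrix(NA_character_, max_steps, n)
    split_members <- character(0)
    split_until <- -1
    split_side <- 1
    split_events <- list()
    step <- 0L
    repeat {
      step <- step + 1L
      if (step > max_steps)
        stop("flight did not reach home within the step budget; ",
             "check the configuration", call. = FALSE)
      s_axis <- (pos[, 1] - 0) * geo$u[1] + pos[, 2] * geo$u[2]
      hab <- .habitat_at(bands, s_axis)
      speed <- config$base_speed + config$habitat_speed_offsets[hab] +
        loft_sp + bird_sp + wob_sp
      flap <- config$base_flap + config$habitat_flap_offsets[hab] +
        loft_fl + bird_fl + wob_fl
      flap <- pmin(pmax(flap, 3), 12)
      pos_hist[[step]] <- pos
      flp_hist[step, ] <- flap
      hab_hist[step, ] <- hab

      # split bookkeeping
      in_split <- (ids %in% split_members) & (step <= split_until)
      if (!any(in_split) && length(split_members)) split_members <- character(0)
      if (!length(split_members) && n >= 4 &&
          runif(1) < config$split_probability_per_min * dt / 60) {
        k <- max(1L, n %/% 3L)
        split_members <- sample(ids, k)
        split_until <- step + round(config$split_duration_s / dt)
        split_side <- sample(c(-1, 1), 1)
        split_events[[length(split_events) + 1L]] <-
          list(step = step, members = split_members, side = split_side,
               duration_s = config$split_duration_s)
        in_split <- ids %in% split_members
      }

      main <- !in_split
      ctr_main <- colMeans(pos[main, , drop = FALSE])
      ctr_split <- if (any(in_split))
        colMeans(pos[in_split, , drop = FALSE]) else NULL
      hab_ctr <- .habitat_at(bands,
                             sum(ctr_main * geo$u))
      spacing <- spacing0 * config$habitat_spread_multipliers[[hab_ctr]]

      # lateral offset of the split subgroup from the main centroid
      lat_off <- if (!is.null(ctr_split))
        abs(sum((ctr_split - ctr_main) * geo$w)) else 0

      # station-keeping (optional): birds ahead of their group's centroid
      # (along the mean travel direction) slow down, trailing birds speed
      # up; bounded and zero-mean across the flock so injected offsets pass
      # through
      if (config$speed_match_ms > 0) {
        dmean <- colMeans(dir)
        dmean <- dmean / max(sqrt(sum(dmean^2)), 1e-9)
        for (i in seq_len(n)) {
          ctr_i <- if (in_split[i]) ctr_split else ctr_main
          proj <- sum((pos[i, ] - ctr_i) * dmean)
          speed[i] <- speed[i] -
            config$speed_match_ms * tanh(proj / (2 * spacing))
        }
      }
      speed <- pmin(pmax(speed, 5), 30)
      spd_hist[step, ] <- speed

      tgt <- matrix(0, n, 2)
      for (i in seq_len(n)) {
        hvec <- home - pos[i, ]
        hvec <- hvec / max(sqrt(sum(hvec^2)), 1e-9)
        ctr <- if (in_split[i]) ctr_split else ctr_main
        cvec <- ctr - pos[i, ]
        dci <- sqrt(sum(cvec^2))
        coh <- if (dci > 1e-9) {
          f <- config$cohesion_strength * (dci - spacing) / max(spacing, 1)
          f <- max(min(f, 1.5), -0.5)
          f * cvec / dci
        } else c(0, 0)
        bias <- if (in_split[i] && lat_off < config$split_offset_m)
          0.3 * split_side * geo$w else c(0, 0)
        v <- hvec + coh + bias + rnorm(2, 0, config$heading_noise_sd)
        tgt[i, ] <- v / max(sqrt(sum(v^2)), 1e-9)
      }
      dir <- 0.7 * dir + 0.3 * tgt
      dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
      pos <- pos + dir * speed * dt
      wob_sp <- phi * wob_sp + rnorm(n, 0, innov_sp)
      wob_fl <- phi * wob_fl + rnorm(n, 0, innov_fl)

      dist_home <- sqrt(rowSums(sweep(pos, 2, home)^2))
      if (all(dist_home < 200)) break
    }
    S <- step
    spd_hist <- spd_hist[seq_len(S), , drop = FALSE]
    flp_hist <- flp_hist[seq_len(S), , drop = FALSE]
    hab_hist <- hab_hist[seq_len(S), , drop = FALSE]
    tt <- t0 + (seq_len(S) - 1L) * dt
    org <- geo$origin_lonlat

    gps <- stats::setNames(vector("list", n), ids)
    for (i in seq_len(n)) {
      xy <- t(vapply(seq_len(S), function(s) pos_hist[[s]][i, ],
                     numeric(2)))
      noisy <- xy + matrix(rnorm(2 * S, 0, config$gps_noise_sd), S, 2)
      ll <- unproject_from_plane(data.frame(x = noisy[, 1],
                                            y = noisy[, 2]), org)
      gps[[i]] <- data.frame(t = tt, lon = ll$lon, lat = ll$lat)
    }

    accel <- NULL
    if (with_accel) {
      accel <- stats::setNames(vector("list", n), ids)
      n100 <- S * 20L
      t100 <- t0 + (seq_len(n100) - 1L) * 0.01
      for (i in seq_len(n)) {
        f100 <- approx(tt, flp_hist[, i], xout = t100, rule = 2)$y
        phase <- 2 * pi * cumsum(f100) * 0.01
        drift <- config$drift_amplitude_g *
          sin(2 * pi * (t100 - t0) / config$drift_period_s)
        z <- 1 + config$flap_amplitude * sin(phase) + drift +
          rnorm(n100, 0, config$accel_noise_sd)
        accel[[i]] <- data.frame(t = t100, z = z)
        attr(accel[[i]], "sample_rate_hz") <- 100
      }
    }

    truth <- list(flock_id = flock_id, flight_idx = flight_idx,
                  flight_date = as.character(date), t0 = t0, dt = dt,
                  bird_ids = ids,
                  speed = spd_hist, flap = flp_hist, habitat = hab_hist,
                  loft_speed_intercept = loft_sp,
                  loft_flap_intercept = loft_fl,
                  bird_speed_intercepts = bird_sp,
                  bird_flap_intercepts = bird_fl,
                  habitat_speed_offsets = config$habitat_speed_offsets,
                  habitat_flap_offsets = config$habitat_flap_offsets,
                  splits = split_events)
    list(gps = gps, accel = accel, truth = truth)
  })
}

#' Simulate a full release campaign
#'
#' All flocks, all flights, over one shared landscape. When `out_dir` is
#' given, per-bird per-flight GPS and accelerometry CSVs, the landscape
#' GeoJSON and a ground-truth JSON are written in the dialects the pipeline
#' consumes; otherwise everything stays in memory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @param with_accel synthesise accelerometry (default `TRUE`).
#' @return (invisibly when writing) list with `landscape`, `flights`
#'   (nested flock -> flight), and `truth` (campaign-level ground truth).
#' @export
simulate_campaign <- function(config, out_dir = NULL, with_accel = TRUE) {
  landscape <- make_landscape(config)
  flocks <- names(config$birds_per_flock)
  flights <- stats::setNames(vector("list", length(flocks)), flocks)
  for (fi in seq_along(flocks)) {
    fl <- flocks[fi]
    flights[[fl]] <- vector("list", config$n_flights)
    for (k in seq_len(config$n_flights)) {
      sd <- config$seed * 10000L + fi * 100L + k
      flights[[fl]][[k]] <- simulate_flight(config, landscape, fl, k,
                                            seed = sd,
                                            with_accel = with_accel)
    }
  }
  truth <- list(
    config = config[c("n_flights", "birds_per_flock", "base_speed",
                      "base_flap", "habitat_speed_offsets",
                      "habitat_flap_offsets", "iteration_spread_trend",
                      "seed")],
    intercepts = .draw_intercepts(config),
    splits = lapply(flights, function(fl)
      lapply(fl, function(x) x$truth$splits)))
  out <- list(landscape = landscape, flights = flights, truth = truth,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_habitat_geojson(landscape, file.path(out_dir, "landscape.geojson"))
    for (fl in flocks) {
      for (k in seq_len(config$n_flights)) {
        fdat <- flights[[fl]][[k]]
        tag <- sprintf("%s_flight%02d", fl, k)
        for (b in names(fdat$gps)) {
          g <- fdat$gps[[b]]
          write.csv(data.frame(timestamp = g$t, lon = g$lon, lat = g$lat),
                    file.path(out_dir, sprintf("%s_%s_gps.csv", tag, b)),
                    row.names = FALSE)
          if (!is.null(fdat$accel)) {
            a <- fdat$accel[[b]]
            write.csv(data.frame(timestamp = a$t, z = a$z),
                      file.path(out_dir,
                                sprintf("%s_%s_accel.csv", tag, b)),
                      row.names = FALSE)
          }
        }
      }
    }
    # named atomic vectors must become JSON objects, not bare arrays
    as_jsonable <- function(x) {
      if (is.list(x)) lapply(x, as_jsonable)
      else if (!is.null(names(x))) as.list(x)
      else x
    }
    jsonlite::write_json(as_jsonable(truth),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
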