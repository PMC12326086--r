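# End-to-end orchestration: biologger streams -> per-second track records ->
# flock frames -> habitat labels -> subsampling -> model selection, with a
# reproducible run manifest.

.default_candidate_terms <- c("habitat", "flight_time", "iteration",
                              "habitat:flight_time", "habitat:iteration")

# rbind data.frames with possibly differing columns, padding with NA
.rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[cols]
  }))
}

.default_responses <- c("flap_frequency", "absolute_spread",
                        "distance_to_centroid", "group_size",
                        "flight_speed", "front_back", "left_right")

#' Validate and normalise a pipeline configuration
#'
#' Accepts a list or a YAML/JSON file path; fills defaults (trim radius
#' 200 m, 10 m cohesion link, 40 m centroid exclusion, 15-sample flap
#' windows, subsample rate 15), rejects unknown keys and non-positive
#' constants.
#'
#' @param config list, YAML/JSON path, or `NULL` for pure defaults.
#' @return normalised `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  config <- config %||% list()
  defaults <- list(
    trim_radius_m = 200, link_dist_m = 10, excl_dist_m = 40,
    flap_window = 15, subsample_rate = 15,
    detrend_window_s = 1, butter_order = 2, butter_cutoff_hz = 1,
    prominence_factor = 0.3, speed_ceiling_ms = 50,
    vif_threshold = 5, cooks_threshold = NULL, stationary_m = 0.5,
    responses = .default_responses,
    transforms = list(absolute_spread = "sqrt",
                      distance_to_centroid = "sqrt"),
    candidate_terms = .default_candidate_terms,
    sites = NULL, paths = NULL, sim = NULL, seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  pos_keys <- c("trim_radius_m", "link_dist_m", "excl_dist_m", "flap_window",
                "subsample_rate", "detrend_window_s", "butter_order",
                "butter_cutoff_hz", "prominence_factor", "speed_ceiling_ms",
                "vif_threshold", "stationary_m")
  for (k in pos_keys)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("configuration constant '", k, "' must be positive", call. = FALSE)
  bad <- setdiff(cfg$responses, .default_responses)
  if (length(bad))
    stop("unknown response(s): ", paste(bad, collapse = ", "), call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

# Read a campaign directory written by simulate_campaign(): per-bird CSVs
# named <flock>_flightNN_<bird>_{gps,accel}.csv plus landscape.geojson.
.read_campaign <- function(dir, sites) {
  gps_files <- list.files(dir, pattern = "_gps\\.csv$", full.names = TRUE)
  if (!length(gps_files)) stop("no *_gps.csv files in ", dir, call. = FALSE)
  landscape <- load_habitat_geojson(file.path(dir, "landscape.geojson"))
  parse1 <- function(f) {
    m <- regmatches(basename(f),
                    regexec("^([A-Za-z]+)_flight(\\d+)_(\\w+)_gps\\.csv$",
                            basename(f)))[[1]]
    if (!length(m)) stop("unrecognised file name: ", basename(f),
                         call. = FALSE)
    list(flock = m[2], flight = as.integer(m[3]), bird = m[4], path = f)
  }
  meta <- lapply(gps_files, parse1)
  flocks <- sort(unique(vapply(meta, `[[`, character(1), "flock")))
  flights <- stats::setNames(vector("list", length(flocks)), flocks)
  start_date <- as.Date("2022-11-10")
  for (fl in flocks) {
    ks <- sort(unique(vapply(Filter(function(m) m$flock == fl, meta),
                             `[[`, integer(1), "flight")))
    flights[[fl]] <- vector("list", max(ks))
    for (k in ks) {
      sel <- Filter(function(m) m$flock == fl && m$flight == k, meta)
      gps <- list(); accel <- list()
      for (m in sel) {
        date <- start_date + (k - 1L)
        g <- read_gps(m$path, m$bird, fl, date)
        gps[[m$bird]] <- data.frame(t = g$t, lon = g$lon, lat = g$lat)
        apath <- sub("_gps\\.csv$", "_accel.csv", m$path)
        if (file.exists(apath)) {
          a <- read_accel(apath, m$bird, date)
          accel[[m$bird]] <- data.frame(t = a$t, z = a$z)
          attr(accel[[m$bird]], "sample_rate_hz") <-
            attr(a, "sample_rate_hz")
        }
      }
      flights[[fl]][[k]] <- list(
        gps = gps, accel = if (length(accel)) accel else NULL,
        truth = list(flight_date = as.character(start_date + (k - 1L)),
                     flight_idx = k))
    }
  }
  list(landscape = landscape, flights = flights,
       config = list(release = sites$release, home = sites$home))
}

#' Process a campaign into track records, flock frames and model reports
#'
#' The core pipeline: projection about the home site, per-fix speed,
#' 200 m release/home trimming (accelerometry trimmed to the same span),
#' flap-frequency extraction, per-second median reduction, flock geometry,
#' habitat labels, stream merging, temporal indices, subsampling,
#' diagnostics, and per-response model selection.
#'
#' @param campaign a campaign from [simulate_campaign()] or
#'   an equivalent structure read from disk.
#' @param config a [validate_config()] result (or `NULL` for defaults).
#' @param fit_models run the model-selection stage (default `TRUE`).
#' @return list with `track` (per-second, pre-subsample), `track_sub`
#'   (post-subsample), `frames` (per-member flock frames), `diagnostics`
#'   (autocorrelation + layer independence), `models` (per-response
#'   `model_report`s) and `manifest` (row counts per stage, seed).
#' @export
process_campaign <- function(campaign, config = NULL, fit_models = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  scfg <- campaign$config
  release_ll <- c(scfg$release[["lon"]], scfg$release[["lat"]])
  home_ll <- c(scfg$home[["lon"]], scfg$home[["lat"]])
  origin <- home_ll
  rel_xy <- project_to_plane(data.frame(lon = release_ll[1],
                                        lat = release_ll[2]), origin)
  release_xy <- c(rel_xy$x, rel_xy$y)
  home_xy <- c(0, 0)
  landscape <- campaign$landscape

  all_records <- list()
  all_frames <- list()
  counts <- list()
  for (fl in names(campaign$flights)) {
    for (k in seq_along(campaign$flights[[fl]])) {
      fdat <- campaign$flights[[fl]][[k]]
      if (is.null(fdat)) next
      fdate <- fdat$truth$flight_date %||% as.character(k)
      per_bird <- list()
      for (b in names(fdat$gps)) {
        g <- fdat$gps[[b]]
        tr <- project_to_plane(g, origin)
        sp <- compute_speed(tr, cfg$speed_ceiling_ms)
        tr$speed <- sp$speed
        tr <- trim_radius(tr, list(release_xy, home_xy), cfg$trim_radius_m)
        if (!nrow(tr)) next
        span <- attr(tr, "span")
        ps <- to_per_second(tr, c("x", "y", "speed"))
        flap_ps <- NULL
        if (!is.null(fdat$accel) && !is.null(fdat$accel[[b]])) {
          a <- fdat$accel[[b]]
          a <- a[a$t >= span[1] & a$t <= span[2], , drop = FALSE]
          if (nrow(a) > 200) {
            flap_ps <- flap_frequency_per_second(
              a, attr(fdat$accel[[b]], "sample_rate_hz"),
              detrend_window_s = cfg$detrend_window_s,
              window_len = cfg$flap_window,
              butter_order = cfg$butter_order,
              butter_cutoff_hz = cfg$butter_cutoff_hz,
              prominence_factor = cfg$prominence_factor)
          }
        }
        per_bird[[b]] <- list(ps = ps, flap = flap_ps)
      }
      if (!length(per_bird)) next
      pos_df <- do.call(rbind, lapply(names(per_bird), function(b) {
        ps <- per_bird[[b]]$ps
        ok <- !is.na(ps$x) & !is.na(ps$y)
        data.frame(bird_id = b, t = ps$t[ok], x = ps$x[ok], y = ps$y[ok],
                   stringsAsFactors = FALSE)
      }))
      frames <- flock_frames(pos_df, release_xy, home_xy,
                             cfg$link_dist_m, cfg$excl_dist_m,
                             cfg$stationary_m)
      if (nrow(frames)) {
        frames$flock_id <- fl
        frames$flight_date <- fdate
        all_frames[[paste(fl, k)]] <- frames
      }
      recs <- lapply(names(per_bird), function(b) {
        ps <- per_bird[[b]]$ps
        ll <- unproject_from_plane(data.frame(x = ps$x, y = ps$y), origin)
        gps_s <- data.frame(bird_id = b, flight_date = fdate, t = ps$t,
                            x = ps$x, y = ps$y, flight_speed = ps$speed,
                            stringsAsFactors = FALSE)
        hab_s <- data.frame(bird_id = b, flight_date = fdate, t = ps$t,
                            habitat = classify_point(landscape, ll$lon,
                                                     ll$lat),
                            stringsAsFactors = FALSE)
        flap_s <- if (!is.null(per_bird[[b]]$flap) &&
                      nrow(per_bird[[b]]$flap))
          cbind(bird_id = b, flight_date = fdate, per_bird[[b]]$flap)
        else NULL
        flock_s <- if (nrow(frames)) {
          fb <- frames[frames$bird_id == b,
                       c("t", "group_size", "absolute_spread",
                         "distance_to_centroid", "front_back",
                         "left_right", "position")]
          if (nrow(fb)) cbind(bird_id = b, flight_date = fdate, fb)
          else NULL
        } else NULL
        m <- merge_streams(gps_s, flap_s, hab_s, flock_s)
        m$flock_id <- fl
        m$loft_id <- fl
        m
      })
      all_records[[paste(fl, k)]] <- .rbind_fill(recs)
    }
  }
  track <- .rbind_fill(all_records)
  rownames(track) <- NULL
  track <- attach_indices(track)
  needed <- setdiff(c("flap_frequency", "group_size", "absolute_spread",
                      "distance_to_centroid", "front_back", "left_right",
                      "position"), names(track))
  for (nm in needed) track[[nm]] <- NA
  track_sub <- subsample_records(track, cfg$subsample_rate)
  frames_all <- do.call(rbind, all_frames)
  rownames(frames_all) <- NULL

  acf1 <- function(df) {
    key <- interaction(df$bird_id, df$flight_date, drop = TRUE)
    vals <- tapply(seq_len(nrow(df)), key, function(ii) {
      s <- df$flap_frequency[ii][order(df$t[ii])]
      if (sum(!is.na(s)) > 20 && sd(s, na.rm = TRUE) > 0)
        autocorrelation(s, 1) else NA_real_
    })
    median(unlist(vals), na.rm = TRUE)
  }
  diagnostics <- list(
    flap_acf1_pre = if (any(!is.na(track$flap_frequency)))
      acf1(track) else NA_real_,
    flap_acf1_post = if (any(!is.na(track_sub$flap_frequency)))
      acf1(track_sub) else NA_real_,
    layer_vs_bird = tryCatch(layer_independence_check(track, "bird_id"),
                             error = function(e) conditionMessage(e)),
    layer_vs_loft = tryCatch(layer_independence_check(track, "loft_id"),
                             error = function(e) conditionMessage(e)))

  models <- NULL
  if (fit_models) {
    models <- stats::setNames(vector("list", length(cfg$responses)),
                              cfg$responses)
    for (resp in cfg$responses) {
      if (all(is.na(track_sub[[resp]]))) {
        models[[resp]] <- structure(
          list(response = resp, status = "no_data"),
          class = "model_report")
        next
      }
      tf <- cfg$transforms[[resp]] %||% "identity"
      models[[resp]] <- tryCatch(
        select_model(track_sub, resp, cfg$candidate_terms, tf,
                     vif_threshold = cfg$vif_threshold,
                     cooks_threshold = cfg$cooks_threshold),
        error = function(e) structure(
          list(response = resp, status = "error",
               message = conditionMessage(e)),
          class = "model_report"))
    }
  }
  manifest <- list(
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    n_track_rows = nrow(track),
    n_subsampled_rows = nrow(track_sub),
    n_frame_rows = if (is.null(frames_all)) 0L else nrow(frames_all),
    responses = cfg$responses,
    constants = cfg[c("trim_radius_m", "link_dist_m", "excl_dist_m",
                      "flap_window", "subsample_rate")])
  list(track = track, track_sub = track_sub, frames = frames_all,
       diagnostics = diagnostics, models = models, manifest = manifest)
}

#' Run the full pipeline from a configuration
#'
#' Simulates a campaign (when `sim` settings are given) or reads one from
#' `paths$data_dir`, processes it, and optionally writes the per-second
#' track tables (pre- and post-subsample), flock frames, per-response model
#' coefficient tables, diagnostics and a run manifest.
#'
#' @param config list or YAML/JSON path accepted by [validate_config()].
#'   `sim` holds [sim_config()] arguments; `paths$data_dir` a campaign
#'   directory; `sites` the release/home coordinates when reading from disk.
#' @param out_dir optional output directory.
#' @return the [process_campaign()] result, invisibly when writing.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  campaign <- if (!is.null(cfg$paths))
    .read_campaign(cfg$paths$data_dir, cfg$sites)
  else {
    sim_args <- cfg$sim %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    simulate_campaign(do.call(sim_config, sim_args))
  }
  res <- process_campaign(campaign, cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_track_table(res$track, file.path(out_dir, "track_per_second.csv"))
    write_track_table(res$track_sub,
                      file.path(out_dir, "track_subsampled.csv"))
    if (!is.null(res$frames))
      write_track_table(res$frames, file.path(out_dir, "flock_frames.csv"))
    for (resp in names(res$models)) {
      rep_ <- res$models[[resp]]
      if (identical(rep_$status, "ok"))
        write.csv(rep_$table,
                  file.path(out_dir, sprintf("model_%s.csv", resp)),
                  row.names = FALSE)
    }
    jsonlite::write_json(
      list(manifest = res$manifest,
           diagnostics = lapply(res$diagnostics, function(d)
             if (is.list(d)) d else as.character(d)),
           selection = lapply(res$models, function(m)
             list(response = m$response, status = m$status,
                  terms = if (identical(m$status, "ok"))
                    m$final$terms else NULL))),
      file.path(out_dir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
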