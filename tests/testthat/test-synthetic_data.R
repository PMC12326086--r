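test_that("landscape generation is deterministic and covers all categories", {
  cfg <- tiny_config(seed = 41)
  land <- make_landscape(cfg)
  p1 <- tempfile(fileext = ".geojson"); p2 <- tempfile(fileext = ".geojson")
  write_habitat_geojson(land, p1)
  write_habitat_geojson(make_landscape(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))     # byte-identical

  bands <- attr(land, "bands")
  L <- attr(land, "frame")$L
  cover <- vapply(c("open", "wooded", "urban"), function(cc) {
    sel <- bands$category == cc
    sum(pmax(0, pmin(bands$end[sel], L) - pmax(bands$start[sel], 0)))
  }, numeric(1)) / L
  expect_equal(sum(cover), 1, tolerance = 1e-9)      # partition of corridor
  expect_true(all(cover >= 0.15))

  # a straight release-to-home segment crosses all three categories
  geo <- attr(land, "frame")
  s <- seq(0, L, length.out = 400)
  pts <- cbind(s * geo$u[1], s * geo$u[2])
  ll <- unproject_from_plane(data.frame(x = pts[, 1], y = pts[, 2]),
                             geo$origin_lonlat)
  cats <- classify_point(land, ll$lon, ll$lat)
  expect_setequal(unique(cats), c("open", "wooded", "urban"))
})

test_that("a degenerate noiseless configuration reproduces its inputs", {
  cfg <- sim_config(n_flights = 1, birds_per_flock = c(L = 3),
                    corridor_length_m = 1200,
                    habitat_speed_offsets = c(open = 0, wooded = 0, urban = 0),
                    habitat_flap_offsets = c(open = 0, wooded = 0, urban = 0),
                    bird_speed_sd = 0, loft_speed_sd = 0,
                    bird_flap_sd = 0, loft_flap_sd = 0,
                    wobble_sd_speed = 0, wobble_sd_flap = 0,
                    gps_noise_sd = 0, accel_noise_sd = 0,
                    heading_noise_sd = 0, drift_amplitude_g = 0,
                    cohesion_strength = 0, speed_match_ms = 0,
                    split_probability_per_min = 0, seed = 42)
  land <- make_landscape(cfg)
  f <- simulate_flight(cfg, land, "L", 1, seed = 7)

  g <- f$gps[[1]]
  org <- c(cfg$home[["lon"]], cfg$home[["lat"]])
  tr <- project_to_plane(g, org)
  sp <- compute_speed(tr)
  expect_lt(max(abs(sp$speed[-1] - cfg$base_speed)), 1e-3)

  ps <- flap_frequency_per_second(f$accel[[1]], 100)
  interior <- ps[ps$t > min(ps$t) + 1 & ps$t < max(ps$t) - 1, ]
  expect_lt(max(abs(interior$flap_frequency - cfg$base_flap)), 0.05)
})

test_that("an injected urban flap offset is recovered by construction", {
  cfg <- sim_config(n_flights = 1, birds_per_flock = c(L = 2),
                    corridor_length_m = 2500,
                    habitat_flap_offsets = c(open = 0, wooded = 0,
                                             urban = -0.10),
                    habitat_speed_offsets = c(open = 0, wooded = 0, urban = 0),
                    bird_flap_sd = 0, loft_flap_sd = 0, wobble_sd_flap = 0,
                    bird_speed_sd = 0, loft_speed_sd = 0, wobble_sd_speed = 0,
                    gps_noise_sd = 0, accel_noise_sd = 0,
                    drift_amplitude_g = 0,
                    split_probability_per_min = 0, seed = 43)
  land <- make_landscape(cfg)
  f <- simulate_flight(cfg, land, "L", 1, seed = 9)
  tr <- f$truth
  tt <- tr$t0 + (seq_len(nrow(tr$flap)) - 1) * 0.2
  sec <- floor(tt)
  hab_ps <- tapply(tr$habitat[, 1], sec, function(h)
    names(which.max(table(h))))
  est <- flap_frequency_per_second(f$accel[[1]], 100)
  m <- merge(data.frame(t = as.numeric(names(hab_ps)),
                        hab = as.character(hab_ps)), est, by = "t")
  contrast <- mean(m$flap_frequency[m$hab == "urban"]) -
    mean(m$flap_frequency[m$hab == "open"])
  expect_equal(contrast, -0.10, tolerance = 0.02)
})

test_that("flights are reproducible under a fixed seed", {
  cfg <- tiny_config(seed = 44)
  land <- make_landscape(cfg)
  f1 <- simulate_flight(cfg, land, "L", 1, seed = 5)
  f2 <- simulate_flight(cfg, land, "L", 1, seed = 5)
  expect_identical(f1$gps, f2$gps)
  expect_identical(f1$accel, f2$accel)
  expect_identical(f1$truth$speed, f2$truth$speed)
})

test_that("simulated physiology stays within plausible bounds", {
  cfg <- recovery_config(seed = 45)
  cfg$n_flights <- 1
  land <- make_landscape(cfg)
  f <- simulate_flight(cfg, land, "N", 1, seed = 45)
  expect_true(all(f$truth$flap >= 3 & f$truth$flap <= 12))
  expect_true(all(f$truth$speed >= 5 & f$truth$speed <= 30))
  # birds start at the release and terminate within 200 m of home
  geo <- attr(land, "frame")
  org <- geo$origin_lonlat
  for (g in f$gps) {
    p <- project_to_plane(g, org)
    d_end <- sqrt((p$x[nrow(p)] - geo$home_xy[1])^2 +
                    (p$y[nrow(p)] - geo$home_xy[2])^2)
    expect_lt(d_end, 220)
  }
})

test_that("campaigns write the full file manifest and ground truth", {
  cfg <- tiny_config(seed = 46)
  out <- tempfile("campaign")
  camp <- simulate_campaign(cfg, out_dir = out, with_accel = FALSE)
  gps_files <- list.files(out, pattern = "_gps\\.csv$")
  expect_length(gps_files, sum(cfg$birds_per_flock) * cfg$n_flights)
  expect_true(file.exists(file.path(out, "landscape.geojson")))

  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, cfg$seed)
  expect_equal(unlist(truth$config$habitat_speed_offsets),
               cfg$habitat_speed_offsets)
  ints <- flocktrace:::.draw_intercepts(cfg)
  expect_equal(unlist(truth$intercepts$bird_speed), ints$bird_speed,
               tolerance = 1e-9)
})

test_that("an injected iteration trend on spread is recoverable", {
  set.seed(47)
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(n_flights = 15, birds_per_flock = c(L = 6),
                      corridor_length_m = 2000,
                      iteration_spread_trend = -0.01,
                      speed_match_ms = 3,
                      gps_noise_sd = 0.2, split_probability_per_min = 0,
                      seed = 500 + r)
    camp <- simulate_campaign(cfg, with_accel = FALSE)
    org <- c(cfg$home[["lon"]], cfg$home[["lat"]])
    rel <- project_to_plane(data.frame(lon = cfg$release[["lon"]],
                                       lat = cfg$release[["lat"]]), org)
    spread_by_flight <- vapply(seq_len(cfg$n_flights), function(k) {
      f <- camp$flights$L[[k]]
      pos <- do.call(rbind, lapply(names(f$gps), function(b) {
        p <- project_to_plane(f$gps[[b]], org)
        ps <- to_per_second(p, c("x", "y"))
        data.frame(bird_id = b, t = ps$t, x = ps$x, y = ps$y)
      }))
      fr <- flock_frames(pos, c(rel$x, rel$y), c(0, 0))
      mean(fr$absolute_spread)
    }, numeric(1))
    unname(coef(lm(spread_by_flight ~ seq_along(spread_by_flight)))[2]) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
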