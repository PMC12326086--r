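# Shared fixtures and independently written oracles.

write_gps_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# GeoJSON writer for hand-built square/rectangle features
write_square_geojson <- function(squares, path = tempfile(fileext = ".geojson"),
                                 prop = "class") {
  feats <- lapply(squares, function(sq) {
    ring <- lapply(seq_len(nrow(sq$coords)), function(i)
      as.numeric(sq$coords[i, ]))
    props <- list()
    props[[prop]] <- sq$class
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  writeLines(jsonlite::toJSON(
    list(type = "FeatureCollection", features = feats),
    auto_unbox = TRUE, digits = NA), path)
  path
}

square_coords <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side), c(x0, y0))
}

# Independent even-odd ray-casting point-in-polygon oracle
ray_cast_inside <- function(ring, px, py) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

# convex polygon (lon/lat degrees) around a centre
random_convex_ring <- function(cx, cy, r, m = sample(3:8, 1)) {
  ang <- sort(runif(m, 0, 2 * pi))
  ring <- cbind(cx + r * cos(ang), cy + r * sin(ang))
  rbind(ring, ring[1, ])
}

# brute-force flock-geometry oracles (rotation-based, written independently
# of the package's dot-product implementation)
slow_decompose <- function(pos, ctr, heading) {
  theta <- atan2(heading[2], heading[1])
  d <- pos - ctr
  fb <- cos(theta) * d[1] + sin(theta) * d[2]
  # right of travel = clockwise 90 degrees from heading
  lr <- cos(theta - pi / 2) * d[1] + sin(theta - pi / 2) * d[2]
  c(fb = fb, lr = lr, dist = sqrt(sum(d^2)))
}

slow_robust_centroid <- function(pos, excl = 40) {
  keep <- rep(TRUE, nrow(pos))
  repeat {
    if (!any(keep)) return(list(centroid = NULL, keep = keep))
    ctr <- c(mean(pos[keep, 1]), mean(pos[keep, 2]))
    dd <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
    dd[!keep] <- -Inf
    if (max(dd) < excl) return(list(centroid = ctr, keep = keep))
    keep[which.max(dd)] <- FALSE
  }
}

slow_spread <- function(pos, heading) {
  vals <- t(apply(pos, 1, slow_decompose, ctr = c(0, 0), heading = heading))
  diff(range(vals[, "fb"])) + diff(range(vals[, "lr"]))
}

# minimal stand-in fit objects for select_best rule tests
fake_fit <- function(aic, r2, n_terms, singular = FALSE, converged = TRUE) {
  structure(list(response = "y", transform = "identity",
                 terms = if (n_terms) paste0("t", seq_len(n_terms))
                         else character(0),
                 aic = aic, r2 = r2, n_obs = 100L,
                 singular = singular, converged = converged),
            class = "lmm_fit")
}

# small mixed-model dataset with known habitat effects
make_lmm_data <- function(n_per = 60, effects = c(wooded = -0.7, urban = 0.7),
                          bird_sd = 1, loft_sd = 1, resid_sd = 1,
                          n_birds_per_loft = c(L = 6, N = 10, R = 8)) {
  lofts <- rep(names(n_birds_per_loft), n_birds_per_loft)
  birds <- paste0(lofts, unlist(lapply(n_birds_per_loft, seq_len)))
  loft_eff <- stats::setNames(rnorm(3, 0, loft_sd), names(n_birds_per_loft))
  bird_eff <- stats::setNames(rnorm(length(birds), 0, bird_sd), birds)
  rows <- do.call(rbind, lapply(seq_along(birds), function(i) {
    hab <- sample(c("open", "wooded", "urban"), n_per, replace = TRUE)
    data.frame(bird_id = birds[i], loft_id = lofts[i], habitat = hab,
               flight_time = runif(n_per, 0, 500),
               iteration = sample(1:15, n_per, replace = TRUE),
               y = 10 + ifelse(hab == "wooded", effects[["wooded"]],
                               ifelse(hab == "urban", effects[["urban"]], 0)) +
                 loft_eff[lofts[i]] + bird_eff[birds[i]] +
                 rnorm(n_per, 0, resid_sd),
               stringsAsFactors = FALSE)
  }))
  attr(rows, "effects") <- effects
  rows
}

# scaled campaign conditions used by recovery experiments
recovery_config <- function(seed) {
  sim_config(n_flights = 5, gps_noise_sd = 0.2, accel_noise_sd = 0.05,
             split_probability_per_min = 0.02, seed = seed)
}

# tiny/fast campaign for pipeline plumbing tests
tiny_config <- function(seed = 3, with_flights = 1) {
  sim_config(n_flights = with_flights,
             birds_per_flock = c(L = 3, N = 3, R = 3),
             corridor_length_m = 1200, gps_noise_sd = 0.3,
             accel_noise_sd = 0.05, split_probability_per_min = 0,
             seed = seed)
}
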