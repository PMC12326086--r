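test_that("fine land-cover classes map onto the three analysis categories", {
  expect_equal(group_source_classes("Coniferous Woodland"), "wooded")
  expect_equal(group_source_classes("Built-up Areas and Gardens"), "urban")
  expect_equal(group_source_classes("Bracken"), "open")
  expect_equal(group_source_classes("Water"), "open")
  expect_error(group_source_classes("Lava Field"), "Lava Field")
})

test_that("GeoJSON loading preserves features, rejects bad geometry", {
  f1 <- write_square_geojson(list(
    list(class = "Built-up Areas and Gardens",
         coords = square_coords(-0.6, 51.4, 0.01)),
    list(class = "Built-up Areas and Gardens",
         coords = square_coords(-0.58, 51.4, 0.01)),
    list(class = "Built-up Areas and Gardens",
         coords = square_coords(-0.56, 51.4, 0.01))))
  f2 <- write_square_geojson(list(
    list(class = "Coniferous Woodland",
         coords = square_coords(-0.6, 51.45, 0.01)),
    list(class = "Coniferous Woodland",
         coords = square_coords(-0.58, 51.45, 0.01))))
  map <- load_habitat_geojson(c(f1, f2))
  expect_s3_class(map, "habitat_map")
  expect_length(map$polygons, 5)
  cats <- vapply(map$polygons, `[[`, character(1), "category")
  expect_equal(sum(cats == "urban"), 3)
  expect_equal(sum(cats == "wooded"), 2)

  f3 <- write_square_geojson(list(
    list(class = "Martian Regolith", coords = square_coords(0, 0, 1))))
  expect_error(load_habitat_geojson(f3), "Martian Regolith")

  # bow-tie ring is self-intersecting -> rejected with a warning
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  f4 <- write_square_geojson(list(
    list(class = "Water", coords = bow),
    list(class = "Water", coords = square_coords(2, 2, 1))))
  expect_warning(m4 <- load_habitat_geojson(f4), "self-intersecting")
  expect_length(m4$polygons, 1)
})

test_that("point classification applies fallback and precedence rules", {
  f <- write_square_geojson(list(
    list(class = "Built-up Areas and Gardens",
         coords = square_coords(0, 0, 1)),
    list(class = "Coniferous Woodland",
         coords = square_coords(0.5, 0.5, 1))))
  map <- load_habitat_geojson(f)
  expect_equal(classify_point(map, 0.25, 0.25), "urban")
  expect_equal(classify_point(map, 1.25, 1.25), "wooded")
  expect_equal(classify_point(map, 5, 5), "open")       # no polygon -> open
  expect_equal(classify_point(map, 0.75, 0.75), "urban") # overlap precedence
  expect_equal(classify_point(map, 0, 0.5), "urban")     # boundary inside
})

test_that("classification is order-invariant and vectorized = scalar", {
  sqs <- list(
    list(class = "Built-up Areas and Gardens",
         coords = square_coords(0, 0, 1)),
    list(class = "Coniferous Woodland", coords = square_coords(0.5, 0, 1)),
    list(class = "Water", coords = square_coords(-1, 0, 1)))
  m1 <- load_habitat_geojson(write_square_geojson(sqs))
  m2 <- load_habitat_geojson(write_square_geojson(rev(sqs)))
  set.seed(42)
  lon <- runif(300, -1.5, 2); lat <- runif(300, -0.5, 1.5)
  expect_identical(classify_point(m1, lon, lat), classify_point(m2, lon, lat))

  fixes <- data.frame(t = seq_along(lon), lon = lon, lat = lat)
  tr <- classify_track(m1, fixes)
  expect_equal(nrow(tr), 300)
  expect_identical(tr$habitat,
                   vapply(seq_along(lon), function(i)
                     classify_point(m1, lon[i], lat[i]), character(1)))
  expect_equal(nrow(classify_track(m1, fixes[0, ])), 0)
})

test_that("a track crossing a boundary changes category at first contained fix", {
  map <- load_habitat_geojson(write_square_geojson(list(
    list(class = "Built-up Areas and Gardens",
         coords = square_coords(1, -1, 2)))))
  fixes <- data.frame(t = 1:11, lon = seq(0, 2, length.out = 11), lat = 0)
  got <- classify_track(map, fixes)$habitat
  oracle <- ifelse(fixes$lon >= 1, "urban", "open")  # boundary inclusive
  expect_identical(got, oracle)
})

test_that("containment agrees with a ray-casting oracle on random cases", {
  set.seed(7)
  n_cases <- 2000
  mism <- 0
  for (i in seq_len(n_cases)) {
    ring <- random_convex_ring(runif(1, -1, 1), runif(1, 50, 52),
                               runif(1, 0.01, 0.3))
    poly <- list(category = "urban", source_class = "Built-up Areas and Gardens",
                 rings = list(ring))
    map <- structure(list(polygons = list(poly),
                          bbox = c(lon_min = min(ring[, 1]),
                                   lon_max = max(ring[, 1]),
                                   lat_min = min(ring[, 2]),
                                   lat_max = max(ring[, 2])),
                          rejected = character(0)),
                     class = "habitat_map")
    px <- runif(5, min(ring[, 1]) - 0.05, max(ring[, 1]) + 0.05)
    py <- runif(5, min(ring[, 2]) - 0.05, max(ring[, 2]) + 0.05)
    got <- classify_point(map, px, py) == "urban"
    want <- ray_cast_inside(ring, px, py)
    mism <- mism + sum(got != want)
  }
  expect_equal(mism, 0)
})
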