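pos_mat <- function(...) {
  m <- do.call(rbind, list(...))
  rownames(m) <- letters[seq_len(nrow(m))]
  m
}

test_that("cohesive membership is the largest 10 m proximity component", {
  line <- pos_mat(c(0, 0), c(5, 0), c(9, 0), c(50, 0))
  expect_setequal(cohesive_members(line), c("a", "b", "c"))

  chain <- pos_mat(c(0, 0), c(8, 0), c(16, 0))   # 16 m via the middle bird
  expect_setequal(cohesive_members(chain), c("a", "b", "c"))

  apart <- pos_mat(c(0, 0), c(20, 0), c(40, 0))
  expect_length(cohesive_members(apart), 0)
  expect_length(cohesive_members(pos_mat(c(1, 1))), 0)  # singleton: no flock

  # equal-size component tie resolved toward the previous centroid
  two_pairs <- pos_mat(c(0, 0), c(5, 0), c(100, 0), c(105, 0))
  expect_setequal(cohesive_members(two_pairs, prev_centroid = c(102, 0)),
                  c("c", "d"))
  expect_setequal(cohesive_members(two_pairs, prev_centroid = c(2, 0)),
                  c("a", "b"))
})

test_that("robust centroid applies the iterative 40 m exclusion", {
  p1 <- pos_mat(c(0, 0), c(10, 0), c(5, 9))
  r1 <- robust_centroid(p1, rownames(p1))
  expect_equal(r1$centroid, c(5, 3))
  expect_setequal(r1$members, c("a", "b", "c"))

  p2 <- pos_mat(c(0, 0), c(2, 0), c(100, 0))
  r2 <- robust_centroid(p2, rownames(p2))
  expect_equal(r2$centroid, c(1, 0))
  expect_setequal(r2$members, c("a", "b"))

  p3 <- pos_mat(c(7, 7))
  expect_equal(robust_centroid(p3, "a")$centroid, c(7, 7))
})

test_that("travel heading normalises, carries forward, and falls back", {
  expect_equal(travel_heading(c(0, 0), c(3, 4)), c(0.6, 0.8))
  expect_equal(travel_heading(c(0, 0), c(0.1, 0), prev_heading = c(0, 1)),
               c(0, 1))
  expect_equal(travel_heading(NULL, NULL, fallback = c(0, 1)), c(0, 1))
})

test_that("position decomposition matches the axis conventions", {
  d <- decompose_position(c(3, -4), c(0, 0), c(1, 0))
  expect_equal(d$front_back, 3)
  expect_equal(d$left_right, 4)      # right of travel is positive
  expect_equal(d$distance_to_centroid, 5)
  expect_equal(d$position, "front")

  at_ctr <- decompose_position(c(2, 2), c(2, 2), c(1, 0))
  expect_equal(unlist(at_ctr[1:3]), c(front_back = 0, left_right = 0,
                                      distance_to_centroid = 0))
  expect_equal(at_ctr$position, "front")   # tie goes to front

  d2 <- decompose_position(c(-2, 0), c(0, 0), c(0, 1))
  expect_equal(d2$front_back, 0)
  expect_equal(d2$left_right, -2)          # left of a northward flock
  expect_equal(d2$position, "front")
})

test_that("absolute spread adds the along- and across-travel extents", {
  pos <- rbind(c(0, 0), c(10, 2), c(4, -3))
  expect_equal(absolute_spread(pos, c(1, 0)), 15)
  expect_equal(absolute_spread(rbind(c(3, 3), c(3, 3)), c(1, 0)), 0)
  expect_equal(absolute_spread(rbind(c(0, 0), c(6, 0)), c(1, 0)), 6)
  expect_true(is.na(absolute_spread(rbind(c(0, 0)), c(1, 0))))
})

test_that("geometry agrees with brute-force recomputation on random flocks", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(2:10, 1)
    pos <- cbind(runif(n, -60, 60), runif(n, -60, 60))
    rownames(pos) <- paste0("b", seq_len(n))
    th <- runif(1, 0, 2 * pi)
    heading <- c(cos(th), sin(th))

    r <- robust_centroid(pos, rownames(pos))
    o <- slow_robust_centroid(pos)
    expect_setequal(r$members, rownames(pos)[o$keep])
    if (length(r$members)) {
      expect_equal(r$centroid, o$centroid, tolerance = 1e-9)
      # final centroid is the plain mean of the final member set
      expect_equal(r$centroid,
                   colMeans(pos[r$members, , drop = FALSE]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }

    rel <- sweep(pos, 2, colMeans(pos))
    expect_equal(absolute_spread(rel, heading), slow_spread(rel, heading),
                 tolerance = 1e-9)
    for (j in seq_len(n)) {
      d <- decompose_position(pos[j, ], colMeans(pos), heading)
      o2 <- slow_decompose(pos[j, ], colMeans(pos), heading)
      expect_equal(d$front_back, unname(o2["fb"]), tolerance = 1e-9)
      expect_equal(d$left_right, unname(o2["lr"]), tolerance = 1e-9)
      expect_equal(d$front_back^2 + d$left_right^2,
                   d$distance_to_centroid^2, tolerance = 1e-6)
      flipped <- decompose_position(pos[j, ], colMeans(pos), -heading)
      expect_equal(flipped$front_back, -d$front_back, tolerance = 1e-9)
      expect_equal(flipped$left_right, -d$left_right, tolerance = 1e-9)
    }
  }
})

test_that("spread is invariant to translation, relabeling and rigid rotation", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    pos <- cbind(rnorm(n, 0, 20), rnorm(n, 0, 20))
    th <- runif(1, 0, 2 * pi)
    heading <- c(cos(th), sin(th))
    base <- absolute_spread(pos, heading)
    shift <- sweep(pos, 2, c(runif(1, -1e3, 1e3), runif(1, -1e3, 1e3)), `+`)
    expect_equal(absolute_spread(shift, heading), base, tolerance = 1e-9)
    expect_equal(absolute_spread(pos[sample(n), ], heading), base,
                 tolerance = 1e-9)
    phi <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    expect_equal(absolute_spread(pos %*% t(R), as.numeric(R %*% heading)),
                 base, tolerance = 1e-9)
  }
})

test_that("splits are resolved toward the larger subgroup", {
  set.seed(13)
  for (i in 1:40) {
    n1 <- sample(4:7, 1)
    n2 <- sample(2:(n1 - 1), 1)
    g1 <- cbind(rnorm(n1, 0, 3), rnorm(n1, 0, 3))
    off <- runif(1, 200, 500)
    g2 <- cbind(rnorm(n2, off, 3), rnorm(n2, 0, 3))
    pos <- rbind(g1, g2)
    rownames(pos) <- paste0("b", seq_len(n1 + n2))
    r <- robust_centroid(pos, rownames(pos))
    expect_setequal(r$members, paste0("b", seq_len(n1)))
  }
})

test_that("per-second frames carry consistent geometry", {
  # two birds flying east 10 m/s, 6 m apart across-track
  secs <- 0:9
  per_sec <- rbind(
    data.frame(bird_id = "a", t = secs, x = 10 * secs, y = 3),
    data.frame(bird_id = "b", t = secs, x = 10 * secs, y = -3))
  fr <- flock_frames(per_sec, release = c(-100, 0), home = c(200, 0))
  expect_equal(sort(unique(fr$t)), secs)
  expect_true(all(fr$group_size == 2))
  expect_equal(unique(fr$absolute_spread), 6)
  expect_equal(fr$heading_x, rep(1, nrow(fr)), tolerance = 1e-9)
  a <- fr[fr$bird_id == "a", ]
  expect_equal(unique(round(a$left_right, 9)), -3)  # north of an eastward flock
  expect_true(all(fr$front_back^2 + fr$left_right^2 -
                    fr$distance_to_centroid^2 < 1e-6))
})
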