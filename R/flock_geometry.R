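# Per-timestamp flock geometry: cohesive membership, robust centroid,
# direction of travel, spread, and each member's position relative to the
# centroid and travel axis.
#
# A flock at a timestamp is the largest connected component of the 10 m
# proximity graph (birds pairwise within 10 m are linked; chains connect).
# The centroid is the arithmetic mean of member positions with iterative
# exclusion of members 40 m or further away — so when a flock splits, the
# larger subgroup keeps the centroid and the minority is excluded for that
# timestamp only (birds may reintegrate later).

#' Cohesively flying members at one timestamp
#'
#' Builds the proximity graph (an edge for every pair of birds at most
#' `link_dist_m` apart) and returns the largest connected component. A
#' component of size one is not a flock (empty result). Ties between
#' equal-sized components go to the component whose mean position is nearest
#' `prev_centroid`, or nearest the `axis` line (release-to-home) when no
#' previous centroid exists.
#'
#' @param positions numeric matrix (birds x 2) with rownames = bird ids.
#' @param link_dist_m pairwise link distance in metres (default 10).
#' @param prev_centroid previous frame's centroid `c(x, y)`, or `NULL`.
#' @param axis list(`origin` =, `dir` = unit vector) of the release-to-home
#'   line, or `NULL`.
#' @return character vector of member bird ids (possibly empty).
#' @export
cohesive_members <- function(positions, link_dist_m = 10,
                             prev_centroid = NULL, axis = NULL) {
  n <- nrow(positions)
  if (n == 0L) return(character(0))
  ids <- rownames(positions) %||% as.character(seq_len(n))
  if (n == 1L) return(character(0))
  d <- as.matrix(dist(positions))
  adj <- d <= link_dist_m
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  best <- max(sizes)
  if (best < 2L) return(character(0))
  cand <- which(sizes == best)
  if (length(cand) > 1L) {
    score <- vapply(cand, function(cc) {
      ctr <- colMeans(positions[comp == cc, , drop = FALSE])
      if (!is.null(prev_centroid)) {
        sqrt(sum((ctr - prev_centroid)^2))
      } else if (!is.null(axis)) {
        v <- ctr - axis$origin
        abs(v[1] * axis$dir[2] - v[2] * axis$dir[1])   # distance to line
      } else 0
    }, numeric(1))
    cand <- cand[which.min(score)]
  } else {
    cand <- cand[[1]]
  }
  ids[comp == cand]
}

#' Robust flock centroid with iterative 40 m exclusion
#'
#' The centroid is the arithmetic mean of member positions; while any member
#' lies `excl_dist_m` or further from it, the farthest such member is removed
#' and the centroid recomputed, until membership is stable. Removing the
#' farthest member first (rather than every distant member at once) is what
#' weights a split toward its larger subgroup: the centroid walks toward the
#' majority as minority birds drop out one by one. Exclusion applies to this
#' timestamp only.
#'
#' @param positions numeric matrix (birds x 2) with rownames = bird ids.
#' @param members character vector of candidate member ids.
#' @param excl_dist_m exclusion distance in metres (default 40).
#' @return list with `centroid` (length-2 numeric) and `members` (final set);
#'   both `NULL`/empty when every member is excluded.
#' @export
robust_centroid <- function(positions, members, excl_dist_m = 40) {
  mem <- members
  repeat {
    if (!length(mem)) return(list(centroid = NULL, members = character(0)))
    pts <- positions[mem, , drop = FALSE]
    ctr <- colMeans(pts)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    if (max(d) < excl_dist_m)
      return(list(centroid = unname(ctr), members = mem))
    mem <- mem[-which.max(d)]
  }
}

#' Flock direction of travel from stepwise centroid change
#'
#' Normalised displacement between successive centroids. Near-stationary
#' steps (displacement below `stationary_m`) carry the previous heading
#' forward; with no previous heading the release-to-home unit vector is the
#' fallback.
#'
#' @param centroid_now,centroid_next centroids at t and t+1 (`c(x, y)`).
#' @param prev_heading previous unit heading or `NULL`.
#' @param fallback unit vector used when nothing else is available.
#' @param stationary_m displacement threshold in metres (default 0.5).
#' @return unit heading `c(hx, hy)`.
#' @export
travel_heading <- function(centroid_now, centroid_next, prev_heading = NULL,
                           fallback = c(0, 1), stationary_m = 0.5) {
  if (is.null(centroid_now) || is.null(centroid_next))
    return(prev_heading %||% fallback)
  d <- centroid_next - centroid_now
  len <- sqrt(sum(d^2))
  if (len < stationary_m) return(prev_heading %||% fallback)
  unname(d / len)
}

#' Decompose a bird's position about the centroid and travel axis
#'
#' With unit heading h and right vector r = (h_y, -h_x):
#' front-back = d . h (positive ahead), left-right = d . r (positive to the
#' right of travel), distance = ||d||, and position is `"front"` iff
#' front-back >= 0.
#'
#' @param bird_pos `c(x, y)` of the bird.
#' @param centroid `c(x, y)` of the flock centroid.
#' @param heading unit heading `c(hx, hy)`.
#' @return list(`front_back`, `left_right`, `distance_to_centroid`,
#'   `position`).
#' @export
decompose_position <- function(bird_pos, centroid, heading) {
  d <- bird_pos - centroid
  fb <- sum(d * heading)
  lr <- d[1] * heading[2] - d[2] * heading[1]   # d . (h_y, -h_x)
  list(front_back = unname(fb), left_right = unname(lr),
       distance_to_centroid = sqrt(sum(d^2)),
       position = if (fb >= 0) "front" else "back")
}

#' Absolute flock spread
#'
#' Along-travel extent (frontmost minus backmost member) plus across-travel
#' extent (leftmost minus rightmost member), in metres.
#'
#' @param positions numeric matrix (members x 2).
#' @param heading unit heading `c(hx, hy)`.
#' @return spread in metres, or `NA` with fewer than 2 members.
#' @export
absolute_spread <- function(positions, heading) {
  if (is.null(positions) || nrow(positions) < 2L) return(NA_real_)
  fb <- positions[, 1] * heading[1] + positions[, 2] * heading[2]
  lr <- positions[, 1] * heading[2] - positions[, 2] * heading[1]
  (max(fb) - min(fb)) + (max(lr) - min(lr))
}

#' Per-second flock frames for one flock-flight
#'
#' Walks the per-second positions of a flock's birds through cohesive
#' membership, robust centroid, stepwise heading (centroid at t to centroid
#' at t+1; the release-to-home direction seeds the first frame and
#' near-stationary steps carry the heading forward), and the per-member
#' decomposition. Seconds with fewer than two cohesive members yield no
#' frame.
#'
#' @param per_sec data.frame with `bird_id`, `t` (whole seconds), `x`, `y`.
#' @param release,home planar `c(x, y)` coordinates of the two sites.
#' @param link_dist_m,excl_dist_m,stationary_m geometry constants
#'   (defaults 10, 40, 0.5).
#' @return data.frame with one row per member per second: `t`, `bird_id`,
#'   `group_size`, `centroid_x`, `centroid_y`, `heading_x`, `heading_y`,
#'   `absolute_spread`, `distance_to_centroid`, `front_back`, `left_right`,
#'   `position`.
#' @export
flock_frames <- function(per_sec, release, home, link_dist_m = 10,
                         excl_dist_m = 40, stationary_m = 0.5) {
  stopifnot(all(c("bird_id", "t", "x", "y") %in% names(per_sec)))
  axis_dir <- home - release
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  axis <- list(origin = release, dir = axis_dir)
  secs <- sort(unique(per_sec$t))
  # pass 1: membership + centroid per second
  mem_list <- vector("list", length(secs))
  ctr_list <- vector("list", length(secs))
  pos_list <- vector("list", length(secs))
  prev_ctr <- NULL
  for (k in seq_along(secs)) {
    rows <- per_sec[per_sec$t == secs[k], , drop = FALSE]
    pos <- cbind(rows$x, rows$y)
    rownames(pos) <- rows$bird_id
    pos_list[[k]] <- pos
    mem <- cohesive_members(pos, link_dist_m, prev_centroid = prev_ctr,
                            axis = axis)
    rc <- robust_centroid(pos, mem, excl_dist_m)
    if (length(rc$members) < 2L) {
      mem_list[[k]] <- character(0)
      ctr_list[k] <- list(NULL)
    } else {
      mem_list[[k]] <- rc$members
      ctr_list[[k]] <- rc$centroid
      prev_ctr <- rc$centroid
    }
  }
  # pass 2: heading (stepwise centroid change) + per-member decomposition
  out <- vector("list", length(secs))
  prev_heading <- NULL
  for (k in seq_along(secs)) {
    mem <- mem_list[[k]]
    if (length(mem) < 2L) next
    ctr <- ctr_list[[k]]
    nxt <- if (k < length(secs)) ctr_list[[k + 1L]] else NULL
    heading <- travel_heading(ctr, nxt, prev_heading, fallback = axis_dir,
                              stationary_m = stationary_m)
    prev_heading <- heading
    pts <- pos_list[[k]][mem, , drop = FALSE]
    rel <- sweep(pts, 2, ctr)
    spread <- absolute_spread(rel, heading)
    fb <- rel[, 1] * heading[1] + rel[, 2] * heading[2]
    lr <- rel[, 1] * heading[2] - rel[, 2] * heading[1]
    out[[k]] <- data.frame(
      t = secs[k], bird_id = mem, group_size = length(mem),
      centroid_x = ctr[1], centroid_y = ctr[2],
      heading_x = heading[1], heading_y = heading[2],
      absolute_spread = spread,
      distance_to_centroid = sqrt(fb^2 + lr^2),
      front_back = fb, left_right = lr,
      position = ifelse(fb >= 0, "front", "back"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(t = numeric(0), bird_id = character(0),
                      group_size = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), heading_x = numeric(0),
                      heading_y = numeric(0), absolute_spread = numeric(0),
                      distance_to_centroid = numeric(0),
                      front_back = numeric(0), left_right = numeric(0),
                      position = character(0))
  res
}
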