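# Habitat polygon maps: loading GeoJSON land-cover layers, grouping fine
# land-cover classes into the three analysis categories (open/wooded/urban),
# and classifying track points by the ground cover beneath them.
#
# Containment is computed in geographic coordinates (no projection):
# point-in-polygon is projection-invariant for non-degenerate polygons at the
# ~10 km extent this package targets. When categories overlap, precedence is
# urban > wooded > open (built-up cover is the most specific label), and
# points covered by no polygon are labelled open, mirroring the grouping of
# "Unclassified" ground under the open category.

#' Map a fine land-cover class name to an analysis category
#'
#' Groups the Phase-4-style land-cover class names into the three categories
#' used throughout the analysis: `open`, `wooded` or `urban`.
#'
#' @param class_name character vector of land-cover class names.
#' @return character vector of categories (`"open"`, `"wooded"`, `"urban"`).
#' @export
group_source_classes <- function(class_name) {
  stopifnot(is.character(class_name), all(nzchar(class_name)))
  map <- phase4_category_map()
  out <- unname(map[class_name])
  if (anyNA(out))
    stop("unknown land-cover class name(s): ",
         paste(unique(class_name[is.na(out)]), collapse = "; "),
         call. = FALSE)
  out
}

#' The default land-cover class to category mapping
#'
#' @return named character vector: names are fine land-cover classes, values
#'   are `open`/`wooded`/`urban`.
#' @export
phase4_category_map <- function() {
  open <- c("Water", "Acid, Calcareous, and Neutral Grassland",
            "Arable and Horticultural", "Bare Ground", "Bare Sand",
            "Bracken", "Dwarf Shrub Heath", "Fen, Marsh, and Swamp",
            "Improved Grassland", "Scrub", "Unclassified")
  wooded <- c("Broadleaved, Mixed, and Yew Woodland", "Coniferous Woodland")
  urban <- c("Built-up Areas and Gardens")
  stats::setNames(
    c(rep("open", length(open)), rep("wooded", length(wooded)),
      rep("urban", length(urban))),
    c(open, wooded, urban))
}

.close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ], tolerance = 0))) {
    m <- rbind(m, m[1, ])
  }
  m
}

# proper-intersection test between two segments (excluding shared endpoints)
.segments_cross <- function(p1, p2, q1, q2) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.ring_self_intersects <- function(m) {
  n <- nrow(m) - 1L           # closed ring: last vertex repeats the first
  if (n < 4L) return(FALSE)   # triangles cannot self-intersect
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    j <- (i + 2L):jmax
    for (k in j) {
      if (.segments_cross(m[i, ], m[i + 1L, ], m[k, ], m[k + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Load habitat polygons from GeoJSON files
#'
#' Parses RFC 7946 feature collections of polygonal features, grouping each
#' feature's land-cover class into an analysis category. Non-polygonal
#' features are skipped with a warning; rings are closed if the closing
#' vertex is absent; self-intersecting rings are rejected with a logged id.
#'
#' @param paths character vector of GeoJSON file paths.
#' @param mapping named character vector mapping class names to categories
#'   (default [phase4_category_map()]). Alternatively each feature may carry
#'   a `category` property directly.
#' @param class_property name of the feature property holding the land-cover
#'   class name (default `"class"`).
#' @return A `habitat_map` object: list of polygons, each with `category`,
#'   `source_class` and a list of rings (closed lon/lat matrices), plus the
#'   lon/lat bounding box.
#' @export
load_habitat_geojson <- function(paths, mapping = phase4_category_map(),
                                 class_property = "class") {
  polys <- list()
  rejected <- character()
  for (path in paths) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- if (identical(gj$type, "FeatureCollection")) gj$features
             else list(gj)
    for (fi in seq_along(feats)) {
      f <- feats[[fi]]
      geom <- f$geometry %||% f
      gtype <- geom$type
      props <- f$properties %||% list()
      fid <- as.character(f$id %||% props$id %||% sprintf("%s#%d", basename(path), fi))
      if (!gtype %in% c("Polygon", "MultiPolygon")) {
        warning("skipping non-polygonal feature ", fid, " (", gtype, ")",
                call. = FALSE)
        next
      }
      cat_prop <- props$category
      if (is.null(cat_prop)) {
        cls <- props[[class_property]]
        if (is.null(cls))
          stop("feature ", fid, " has neither a '", class_property,
               "' nor a 'category' property", call. = FALSE)
        if (!cls %in% names(mapping))
          stop("unmapped land-cover class: ", cls, call. = FALSE)
        category <- unname(mapping[[cls]])
      } else {
        category <- as.character(cat_prop)
        cls <- as.character(props[[class_property]] %||% category)
      }
      if (!category %in% .habitat_levels)
        stop("unknown category '", category, "' for feature ", fid,
             call. = FALSE)
      coord_sets <- if (gtype == "Polygon") list(geom$coordinates)
                    else geom$coordinates
      for (cs in coord_sets) {
        rings <- lapply(cs, function(r) {
          .close_ring(do.call(rbind, lapply(r, function(p)
            c(as.numeric(p[[1]]), as.numeric(p[[2]])))))
        })
        bad <- vapply(rings, .ring_self_intersects, logical(1))
        if (any(bad)) {
          rejected <- c(rejected, fid)
          warning("rejecting self-intersecting ring(s) in feature ", fid,
                  call. = FALSE)
          next
        }
        polys[[length(polys) + 1L]] <-
          list(category = category, source_class = cls, rings = rings)
      }
    }
  }
  if (!length(polys)) stop("no polygonal features found", call. = FALSE)
  all_xy <- do.call(rbind, unlist(lapply(polys, `[[`, "rings"),
                                  recursive = FALSE))
  out <- structure(
    list(polygons = polys,
         bbox = c(lon_min = min(all_xy[, 1]), lon_max = max(all_xy[, 1]),
                  lat_min = min(all_xy[, 2]), lat_max = max(all_xy[, 2])),
         rejected = rejected),
    class = "habitat_map")
  out
}

#' @export
print.habitat_map <- function(x, ...) {
  tab <- table(vapply(x$polygons, `[[`, character(1), "category"))
  cat("habitat_map:", length(x$polygons), "polygon(s) [",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "]\n")
  cat(sprintf("  bbox lon [%.5f, %.5f], lat [%.5f, %.5f]\n",
              x$bbox["lon_min"], x$bbox["lon_max"],
              x$bbox["lat_min"], x$bbox["lat_max"]))
  invisible(x)
}

# winding-number containment of many points in one closed ring, with
# boundary points (on an edge or vertex) counted as inside
.ring_contains <- function(ring, lon, lat) {
  n <- nrow(ring) - 1L
  wn <- integer(length(lon))
  on_edge <- logical(length(lon))
  eps <- 1e-12
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    cross <- (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1)
    scale <- abs(x2 - x1) + abs(y2 - y1) + 1e-30
    on_seg <- abs(cross) <= eps * scale &
      lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    up <- (y1 <= lat) & (y2 > lat) & (cross > 0)
    dn <- (y1 > lat) & (y2 <= lat) & (cross < 0)
    wn <- wn + up - dn
  }
  (wn != 0L) | on_edge
}

# even-odd containment over a polygon's rings (outer ring + holes)
.poly_contains <- function(poly, lon, lat) {
  inside <- logical(length(lon))
  for (ring in poly$rings) inside <- xor(inside, .ring_contains(ring, lon, lat))
  inside
}

#' Classify points by ground-cover category
#'
#' Returns, for each point, the category of a containing habitat polygon.
#' Points contained in polygons of several categories take the most specific
#' one (urban > wooded > open); points in no polygon are `open`; points on a
#' polygon boundary count as inside.
#'
#' @param map a `habitat_map`.
#' @param lon,lat numeric vectors of WGS84 coordinates.
#' @return character vector of categories, one per point.
#' @export
classify_point <- function(map, lon, lat) {
  stopifnot(inherits(map, "habitat_map"), length(lon) == length(lat))
  if (!length(lon)) return(character(0))
  hit_urban <- logical(length(lon))
  hit_wooded <- logical(length(lon))
  for (poly in map$polygons) {
    if (poly$category == "open") next   # open is also the fallback
    xs <- do.call(rbind, poly$rings)
    cand <- lon >= min(xs[, 1]) - 1e-9 & lon <= max(xs[, 1]) + 1e-9 &
            lat >= min(xs[, 2]) - 1e-9 & lat <= max(xs[, 2]) + 1e-9
    if (!any(cand)) next
    inside <- .poly_contains(poly, lon[cand], lat[cand])
    if (poly$category == "urban") hit_urban[cand] <- hit_urban[cand] | inside
    else hit_wooded[cand] <- hit_wooded[cand] | inside
  }
  out <- rep("open", length(lon))
  out[hit_wooded] <- "wooded"
  out[hit_urban] <- "urban"
  out
}

#' Classify a GPS track by ground cover
#'
#' Point-by-point habitat assignment: element `i` of the result is
#' `classify_point(map, fixes$lon[i], fixes$lat[i])`.
#'
#' @param map a `habitat_map`.
#' @param fixes data.frame with `t`, `lon`, `lat` (ordered by `t`).
#' @return data.frame with columns `t` and `habitat`, same length and order
#'   as `fixes`.
#' @export
classify_track <- function(map, fixes) {
  if (!nrow(fixes))
    return(data.frame(t = numeric(0), habitat = character(0)))
  data.frame(t = fixes$t,
             habitat = classify_point(map, fixes$lon, fixes$lat),
             stringsAsFactors = FALSE)
}

#' Write a habitat map to a GeoJSON file
#'
#' Inverse of [load_habitat_geojson()] for maps built in this package.
#' Output is deterministic: coordinates are printed at fixed precision.
#'
#' @param map a `habitat_map`.
#' @param path output path.
#' @param digits coordinate decimal places (default 8, ~1 mm).
#' @return `path`, invisibly.
#' @export
write_habitat_geojson <- function(map, path, digits = 8) {
  feat <- lapply(map$polygons, function(p) {
    coords <- lapply(p$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i)
        as.numeric(round(r[i, ], digits)))
    })
    list(type = "Feature",
         properties = list(class = p$source_class, category = p$category),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = feat)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
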