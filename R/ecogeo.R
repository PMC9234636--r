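EARTH_RADIUS_KM <- 6371.0088  # authalic mean radius

#' Occurrence point set for geographic gap analysis
#'
#' @param points data frame with columns `lon`, `lat`, `role`
#'   (`"in_situ"` or `"ex_situ_source"`) and `region` (`"East"`/`"West"`)
#' @return a validated `occurrence_set` data frame
#' @export
occurrence_set <- function(points) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "role", "region")
  if (!all(need %in% names(points)))
    stop("occurrence table needs columns ", paste(need, collapse = ", "))
  bad <- which(points$lon < -180 | points$lon > 180 |
                 points$lat < -90 | points$lat > 90 |
                 is.na(points$lon) | is.na(points$lat))
  if (length(bad))
    stop("invalid coordinates at rows: ", paste(bad, collapse = ", "))
  if (!all(points$role %in% c("in_situ", "ex_situ_source")))
    stop("role must be in_situ or ex_situ_source")
  structure(points, class = c("occurrence_set", "data.frame"))
}

#' @rdname occurrence_set
#' @param path CSV path with the same columns
#' @export
read_occurrences <- function(path) {
  occurrence_set(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname occurrence_set
#' @param occ an `occurrence_set`
#' @export
write_occurrences <- function(occ, path) {
  write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Albers equal-area conic projection
#'
#' Spherical Albers projection with standard parallels chosen by the
#' one-sixth rule from the data's latitude range (unless supplied). Output is
#' planar kilometres, so circular buffers of a radius in km can be drawn as
#' planar discs and areas of dissolved buffers are in km^2.
#'
#' @param lonlat two-column matrix or data frame of degrees (lon, lat)
#' @param params optional list with `lon0, lat0, lat1, lat2` (degrees)
#' @return list with `params` and `project(lonlat) -> xy km` function
#' @export
albers_projection <- function(lonlat, params = NULL) {
  ll <- as.matrix(lonlat[, 1:2])
  if (is.null(params)) {
    lat_rng <- range(ll[, 2])
    span <- diff(lat_rng)
    if (span < 1e-6) {
      lat1 <- lat_rng[1] - 1
      lat2 <- lat_rng[2] + 1
    } else {
      lat1 <- lat_rng[1] + span / 6
      lat2 <- lat_rng[2] - span / 6
    }
    params <- list(lon0 = mean(range(ll[, 1])), lat0 = mean(lat_rng),
                   lat1 = lat1, lat2 = lat2)
  }
  d2r <- pi / 180
  phi1 <- params$lat1 * d2r
  phi2 <- params$lat2 * d2r
  phi0 <- params$lat0 * d2r
  lam0 <- params$lon0 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho0 <- EARTH_RADIUS_KM * sqrt(C - 2 * n * sin(phi0)) / n
  project <- function(pts) {
    pts <- as.matrix(pts[, 1:2, drop = FALSE])
    phi <- pts[, 2] * d2r
    lam <- pts[, 1] * d2r
    rho <- EARTH_RADIUS_KM * sqrt(C - 2 * n * sin(phi)) / n
    theta <- n * (lam - lam0)
    cbind(x = rho * sin(theta), y = rho0 - rho * cos(theta))
  }
  list(params = params, project = project)
}

# ---- planar interval machinery for scanline areas ----------------------

# merge intervals given as a 2-column matrix [start, end]; returns same shape
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out_s <- iv[1, 1]
  out_e <- iv[1, 2]
  k <- 1L
  s <- numeric(nrow(iv))
  e <- numeric(nrow(iv))
  s[1] <- out_s
  e[1] <- out_e
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= e[k]) {
      if (iv[i, 2] > e[k]) e[k] <- iv[i, 2]
    } else {
      k <- k + 1L
      s[k] <- iv[i, 1]
      e[k] <- iv[i, 2]
    }
  }
  cbind(s[seq_len(k)], e[seq_len(k)])
}

# intersect two merged interval lists (two-pointer sweep)
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(a[0, , drop = FALSE])
  i <- 1L
  j <- 1L
  s <- numeric(0)
  e <- numeric(0)
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1])
    hi <- min(a[i, 2], b[j, 2])
    if (lo < hi) {
      s <- c(s, lo)
      e <- c(e, hi)
    }
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  cbind(s, e)
}

interval_length <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

# disc-union cross-section at height y: merged x-intervals
disc_slice <- function(xy, r, y) {
  dy <- y - xy[, 2]
  act <- which(abs(dy) < r)
  if (!length(act)) return(matrix(numeric(0), 0, 2))
  half <- sqrt(r^2 - dy[act]^2)
  merge_intervals(cbind(xy[act, 1] - half, xy[act, 1] + half))
}

# scanline grid covering all discs; slices_per_disc controls the midpoint
# integration step (step = 2r / slices_per_disc)
scan_ys <- function(xy_list, r, slices_per_disc = 512L) {
  ally <- unlist(lapply(xy_list, function(m) m[, 2]))
  step <- 2 * r / slices_per_disc
  y0 <- min(ally) - r
  y1 <- max(ally) + r
  seq(y0 + step / 2, y1, by = step)
}

#' Dissolved buffer around occurrence points
#'
#' Projects the points to an equal-area plane, buffers each with a planar
#' disc of the given radius, and dissolves the discs into a single region.
#' The dissolved region's area is evaluated by midpoint scanline integration
#' of the union cross-sections (duplicated coordinates are removed first, so
#' dissolving is idempotent).
#'
#' @param occ an [occurrence_set()]
#' @param radius_km buffer radius in kilometres
#' @param role which points to buffer: `"in_situ"` or `"ex_situ_source"`
#' @param scope `"overall"`, `"East"`, or `"West"`
#' @param projection optional result of [albers_projection()]; defaults to a
#'   projection fitted to all points in `occ` (share one projection across
#'   roles when comparing areas)
#' @param slices_per_disc scanline resolution (integration step
#'   `= 2 * radius / slices_per_disc`)
#' @return a `buffered_range`: list with projected `centers`, `radius_km`,
#'   `area_km2`, and the projection `params`
#' @export
buffer_and_dissolve <- function(occ, radius_km, role = "in_situ",
                                scope = "overall", projection = NULL,
                                slices_per_disc = 512L) {
  if (radius_km <= 0) stop("radius must be positive")
  occ <- occurrence_set(occ)
  projection <- projection %||% albers_projection(occ[, c("lon", "lat")])
  keep <- occ$role == role
  if (scope != "overall") keep <- keep & occ$region == scope
  pts <- occ[keep, c("lon", "lat"), drop = FALSE]
  pts <- unique(pts)
  if (nrow(pts) == 0L)
    stop("no ", role, " points in scope ", scope)
  xy <- projection$project(pts)
  ys <- scan_ys(list(xy), radius_km, slices_per_disc)
  step <- ys[2] - ys[1]
  area <- 0
  for (y in ys) area <- area + interval_length(disc_slice(xy, radius_km, y))
  area <- area * step
  structure(list(centers = xy, radius_km = radius_km, area_km2 = area,
                 params = projection$params, scope = scope, role = role),
            class = "buffered_range")
}

#' Geographic coverage of ex situ source localities
#'
#' Percent of the in situ buffered range that is overlapped by the ex situ
#' source buffered range at a given radius:
#' `100 * area(ex situ buffers intersect in situ buffers) / area(in situ buffers)`.
#' Both dissolved regions and their intersection are integrated on one shared
#' scanline grid in one shared equal-area projection.
#'
#' @inheritParams buffer_and_dissolve
#' @return list with `percent`, `conserved_km2`, `total_km2`, `radius_km`,
#'   `scope`
#' @export
geographic_coverage <- function(occ, radius_km, scope = "overall",
                                projection = NULL, slices_per_disc = 512L) {
  occ <- occurrence_set(occ)
  projection <- projection %||% albers_projection(occ[, c("lon", "lat")])
  sel <- function(role) {
    keep <- occ$role == role
    if (scope != "overall") keep <- keep & occ$region == scope
    pts <- unique(occ[keep, c("lon", "lat"), drop = FALSE])
    if (nrow(pts) == 0L) stop("no ", role, " points in scope ", scope)
    projection$project(pts)
  }
  xy_in <- sel("in_situ")
  xy_ex <- sel("ex_situ_source")
  ys <- scan_ys(list(xy_in, xy_ex), radius_km, slices_per_disc)
  step <- ys[2] - ys[1]
  tot <- 0
  ov <- 0
  for (y in ys) {
    si <- disc_slice(xy_in, radius_km, y)
    tot <- tot + interval_length(si)
    if (nrow(si)) {
      se <- disc_slice(xy_ex, radius_km, y)
      ov <- ov + interval_length(intersect_intervals(si, se))
    }
  }
  tot <- tot * step
  ov <- ov * step
  if (tot <= 0) stop("zero in situ buffered area")
  list(percent = 100 * ov / tot, conserved_km2 = ov, total_km2 = tot,
       radius_km = radius_km, scope = scope)
}

# ---- ecoregion layers ---------------------------------------------------

#' Ecoregion polygon layer
#'
#' A set of polygon features, each carrying a Level-III and a Level-IV
#' identifier (Level IV nests within Level III). Multiple features may share
#' an identifier.
#'
#' @param level3,level4 character identifier vectors, one per feature
#' @param polygons list of rings; each feature is a list of 2-column
#'   lon/lat matrices (outer rings; holes are not modelled)
#' @return an `ecoregion_layer`
#' @export
ecoregion_layer <- function(level3, level4, polygons) {
  if (length(level3) != length(polygons) ||
        length(level4) != length(polygons))
    stop("level identifiers and polygons must have equal length")
  structure(list(level3 = as.character(level3),
                 level4 = as.character(level4),
                 polygons = polygons),
            class = "ecoregion_layer")
}

#' @export
print.ecoregion_layer <- function(x, ...) {
  cat(sprintf(
    "ecoregion_layer: %d features, %d Level-III / %d Level-IV identifiers\n",
    length(x$polygons), length(unique(x$level3)), length(unique(x$level4))))
  invisible(x)
}

#' Read / write an ecoregion layer as GeoJSON
#'
#' Reads Polygon and MultiPolygon features (outer rings only) with the level
#' identifiers taken from the named property fields.
#'
#' @param path GeoJSON file path
#' @param level3_field,level4_field property names holding the Level-III and
#'   Level-IV identifiers
#' @return an [ecoregion_layer()]
#' @export
read_ecoregions_geojson <- function(path, level3_field = "level3",
                                    level4_field = "level4") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  l3 <- character(0)
  l4 <- character(0)
  polys <- list()
  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  for (f in gj$features) {
    geom <- f$geometry
    props <- f$properties
    v3 <- props[[level3_field]]
    v4 <- props[[level4_field]]
    if (is.null(v3) || is.null(v4))
      stop("feature missing level identifier fields '", level3_field,
           "'/'", level4_field, "'")
    rings <- switch(geom$type,
      Polygon = list(ring_to_matrix(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates,
                            function(poly) ring_to_matrix(poly[[1]])),
      stop("unsupported geometry type: ", geom$type))
    l3 <- c(l3, as.character(v3))
    l4 <- c(l4, as.character(v4))
    polys[[length(polys) + 1L]] <- rings
  }
  ecoregion_layer(l3, l4, polys)
}

#' @rdname read_ecoregions_geojson
#' @param layer an [ecoregion_layer()]
#' @export
write_ecoregions_geojson <- function(layer, path) {
  features <- lapply(seq_along(layer$polygons), function(i) {
    rings <- layer$polygons[[i]]
    coords <- lapply(rings, function(m) {
      m <- close_ring(m)
      lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    })
    list(type = "Feature",
         properties = list(level3 = layer$level3[i],
                           level4 = layer$level4[i]),
         geometry = if (length(coords) == 1L)
           list(type = "Polygon", coordinates = list(coords[[1]]))
         else
           list(type = "MultiPolygon",
                coordinates = lapply(coords, list)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

# even-odd point-in-polygon on one ring (planar)
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# min distance from point to ring boundary (planar)
point_ring_dist <- function(px, py, ring) {
  x1 <- ring[, 1]
  y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1])
  y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt(min((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2))
}

# distance from a point to a polygon feature (0 if inside any ring)
point_feature_dist <- function(px, py, rings_xy) {
  d <- Inf
  for (ring in rings_xy) {
    if (point_in_ring(px, py, ring)) return(0)
    d <- min(d, point_ring_dist(px, py, ring))
  }
  d
}

# does the union of discs (centers xy, radius r) intersect the feature with
# nonzero area?  Equivalent to: some center lies within distance < r of the
# feature's area.
feature_hit <- function(xy, r, rings_xy) {
  for (i in seq_len(nrow(xy))) {
    if (point_feature_dist(xy[i, 1], xy[i, 2], rings_xy) < r) return(TRUE)
  }
  FALSE
}

#' Ecoregion coverage of ex situ source localities
#'
#' Counts the distinct ecoregion identifiers (Level III or IV) whose polygons
#' are overlapped (any nonzero-area intersection) by the dissolved in situ
#' buffers, and the subset of those also overlapped by the dissolved ex situ
#' buffers; reports `100 * conserved / total`.
#'
#' @inheritParams buffer_and_dissolve
#' @param layer an [ecoregion_layer()]
#' @param level `"III"` or `"IV"`
#' @return list with `percent`, `conserved`, `total`, `radius_km`, `level`,
#'   `scope`
#' @export
ecoregion_coverage <- function(occ, layer, radius_km, level = c("III", "IV"),
                               scope = "overall", projection = NULL) {
  level <- match.arg(level)
  occ <- occurrence_set(occ)
  projection <- projection %||% albers_projection(occ[, c("lon", "lat")])
  sel <- function(role) {
    keep <- occ$role == role
    if (scope != "overall") keep <- keep & occ$region == scope
    pts <- unique(occ[keep, c("lon", "lat"), drop = FALSE])
    if (nrow(pts) == 0L) stop("no ", role, " points in scope ", scope)
    projection$project(pts)
  }
  xy_in <- sel("in_situ")
  xy_ex <- sel("ex_situ_source")
  ids <- if (level == "III") layer$level3 else layer$level4
  rings_xy <- lapply(layer$polygons, function(rings)
    lapply(rings, projection$project))
  hit_in <- vapply(rings_xy, function(r) feature_hit(xy_in, radius_km, r),
                   logical(1))
  hit_ex <- vapply(rings_xy, function(r) feature_hit(xy_ex, radius_km, r),
                   logical(1))
  total_ids <- unique(ids[hit_in])
  if (!length(total_ids))
    stop("no ecoregions intersect the in situ buffers")
  cons_ids <- intersect(unique(ids[hit_ex]), total_ids)
  list(percent = 100 * length(cons_ids) / length(total_ids),
       conserved = length(cons_ids), total = length(total_ids),
       radius_km = radius_km, level = level, scope = scope)
}

#' Table of geographic and ecoregion coverage across radii and scopes
#'
#' @inheritParams ecoregion_coverage
#' @param radii buffer radii in km
#' @param levels ecoregion levels to include (ignored when `layer` is `NULL`)
#' @param scopes scopes to evaluate
#' @return a data frame with columns
#'   `method, level, radius_km, scope, percent, conserved, total`
#' @export
coverage_report <- function(occ, layer = NULL, radii = c(10, 50, 100),
                            levels = c("III", "IV"),
                            scopes = c("overall", "East", "West")) {
  occ <- occurrence_set(occ)
  projection <- albers_projection(occ[, c("lon", "lat")])
  rows <- list()
  for (r in radii) {
    for (sc in scopes) {
      g <- geographic_coverage(occ, r, sc, projection)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "geographic", level = NA_character_, radius_km = r,
        scope = sc, percent = g$percent, conserved = g$conserved_km2,
        total = g$total_km2, stringsAsFactors = FALSE)
      if (!is.null(layer)) {
        for (lv in levels) {
          e <- ecoregion_coverage(occ, layer, r, lv, sc, projection)
          rows[[length(rows) + 1L]] <- data.frame(
            method = "ecoregion", level = lv, radius_km = r, scope = sc,
            percent = e$percent, conserved = e$conserved, total = e$total,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
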