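occ_at <- function(lonlat, role = "in_situ", region = "East") {
  occurrence_set(data.frame(lon = lonlat[, 1], lat = lonlat[, 2],
                            role = role, region = region))
}

test_that("dissolved buffer areas match analytic disc formulas", {
  # single point: area = pi r^2 within 0.5% (projection + scanline error)
  pt <- cbind(-105, 34)
  for (r in c(10, 50, 100)) {
    br <- buffer_and_dissolve(occ_at(pt), r)
    expect_equal(br$area_km2, pi * r^2, tolerance = 0.005)
  }
  # two points separated by > 2r: two disjoint discs
  r <- 20
  far <- rbind(c(-105, 34), c(-104, 34))  # ~92 km apart
  br2 <- buffer_and_dissolve(occ_at(far), r)
  expect_equal(br2$area_km2, 2 * pi * r^2, tolerance = 0.005)

  # two discs with centres exactly r apart: union from the standard
  # circle-circle intersection (lens) closed form, evaluated independently
  proj <- albers_projection(rbind(c(-105, 34), c(-105, 35)))
  xy0 <- proj$project(cbind(-105, 34))
  # move ~r km north in projected space by inverting the projected offset
  lat_step <- r / 111  # approximate degrees, then refine numerically
  f <- function(dlat) {
    sqrt(sum((proj$project(cbind(-105, 34 + dlat)) - xy0)^2)) - r
  }
  dlat <- uniroot(f, c(lat_step * 0.5, lat_step * 1.5), tol = 1e-12)$root
  two <- rbind(c(-105, 34), c(-105, 34 + dlat))
  d <- r
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expected <- 2 * pi * r^2 - lens
  br3 <- buffer_and_dissolve(occ_at(two), r, projection = proj)
  expect_equal(br3$area_km2, expected, tolerance = 0.005)
})

test_that("geographic coverage honours identity, disjointness, and invariances", {
  pts <- rbind(c(-105, 34), c(-104.4, 34.3), c(-104.9, 33.6))
  both <- rbind(
    data.frame(lon = pts[, 1], lat = pts[, 2], role = "in_situ",
               region = "East"),
    data.frame(lon = pts[, 1], lat = pts[, 2], role = "ex_situ_source",
               region = "East"))
  for (r in c(10, 50, 100)) {
    g <- geographic_coverage(occurrence_set(both), r)
    expect_equal(g$percent, 100, tolerance = 1e-6)
  }
  # disjoint ex situ polygon: 0%
  dis <- rbind(
    data.frame(lon = pts[, 1], lat = pts[, 2], role = "in_situ",
               region = "East"),
    data.frame(lon = -99, lat = 31, role = "ex_situ_source",
               region = "East"))
  expect_equal(geographic_coverage(occurrence_set(dis), 10)$percent, 0)

  # conserved area never exceeds total
  sub <- rbind(
    data.frame(lon = pts[, 1], lat = pts[, 2], role = "in_situ",
               region = "East"),
    data.frame(lon = pts[1, 1], lat = pts[1, 2], role = "ex_situ_source",
               region = "East"))
  for (r in c(10, 50)) {
    g <- geographic_coverage(occurrence_set(sub), r)
    expect_lte(g$conserved_km2, g$total_km2 + 1e-9)
    expect_gt(g$percent, 0)
  }

  # point order and duplicated points do not change the result
  g1 <- geographic_coverage(occurrence_set(sub), 25)
  shuf <- sub[c(4, 2, 1, 3), ]
  dup <- rbind(sub, sub[1, ])
  expect_equal(geographic_coverage(occurrence_set(shuf), 25)$percent,
               g1$percent, tolerance = 1e-12)
  expect_equal(geographic_coverage(occurrence_set(dup), 25)$percent,
               g1$percent, tolerance = 1e-12)
})

test_that("adding an ex situ source point never decreases coverage", {
  set.seed(14)
  base <- cbind(-106 + runif(8), 33 + runif(8))
  occ <- rbind(
    data.frame(lon = base[, 1], lat = base[, 2], role = "in_situ",
               region = "East"),
    data.frame(lon = base[1:2, 1], lat = base[1:2, 2],
               role = "ex_situ_source", region = "East"))
  g0 <- geographic_coverage(occurrence_set(occ), 15)
  occ2 <- rbind(occ, data.frame(lon = base[5, 1], lat = base[5, 2],
                                role = "ex_situ_source", region = "East"))
  g1 <- geographic_coverage(occurrence_set(occ2), 15)
  expect_gte(g1$percent, g0$percent - 1e-9)
})

test_that("grid ecoregion counts match hand counts", {
  # 3x3 unit-degree grid; Level IV = Level III cells here (1 subdivision)
  xs <- seq(-106, -103)
  ys <- seq(33, 36)
  l3 <- character(0)
  polys <- list()
  for (i in 1:3) for (j in 1:3) {
    l3 <- c(l3, sprintf("C%d%d", i, j))
    polys[[length(polys) + 1L]] <- list(rbind(
      c(xs[i], ys[j]), c(xs[i + 1], ys[j]),
      c(xs[i + 1], ys[j + 1]), c(xs[i], ys[j + 1])))
  }
  layer <- ecoregion_layer(l3, l3, polys)
  # in situ points in the centres of 5 distinct cells; ex situ in 2 of them;
  # 1 km buffers cannot reach adjacent cells
  centres <- rbind(c(-105.5, 33.5), c(-104.5, 33.5), c(-103.5, 33.5),
                   c(-105.5, 34.5), c(-105.5, 35.5))
  occ <- rbind(
    data.frame(lon = centres[, 1], lat = centres[, 2], role = "in_situ",
               region = "East"),
    data.frame(lon = centres[1:2, 1], lat = centres[1:2, 2],
               role = "ex_situ_source", region = "East"))
  res <- ecoregion_coverage(occurrence_set(occ), layer, 1, "III")
  expect_equal(res$total, 5L)
  expect_equal(res$conserved, 2L)
  expect_equal(res$percent, 40)
  # a large buffer sweeps in every cell
  res2 <- ecoregion_coverage(occurrence_set(occ), layer, 400, "III")
  expect_equal(res2$total, 9L)
  # conserved set is always a subset of the total set
  expect_lte(res2$conserved, res2$total)
  # identical point sets: 100% at any radius
  both <- rbind(occ[occ$role == "in_situ", ],
                transform(occ[occ$role == "in_situ", ],
                          role = "ex_situ_source"))
  res3 <- ecoregion_coverage(occurrence_set(both), layer, 50, "III")
  expect_equal(res3$percent, 100)
})

test_that("ecoregion GeoJSON round trip preserves ids and geometry", {
  sim <- simulate_dataset(seed = 2, config = sim_config(
    n_pops_east = 3, n_pops_west = 3, n_individuals = 60, n_loci = 3,
    alleles_per_locus = 6, n_singletons = 2))
  layer <- sim$layer
  path <- tempfile(fileext = ".geojson")
  write_ecoregions_geojson(layer, path)
  back <- read_ecoregions_geojson(path)
  expect_equal(back$level3, layer$level3)
  expect_equal(back$level4, layer$level4)
  # rings re-read closed; compare against the closed originals
  for (k in seq_along(back$polygons)) {
    orig <- exsituaudit:::close_ring(layer$polygons[[k]][[1]])
    expect_equal(unname(back$polygons[[k]][[1]]), unname(orig),
                 tolerance = 1e-12)
  }
  # coverage computed on the round-tripped layer is unchanged
  r1 <- ecoregion_coverage(sim$occurrences, layer, 50, "IV")
  r2 <- ecoregion_coverage(sim$occurrences, back, 50, "IV")
  expect_equal(r2$percent, r1$percent)
  expect_equal(r2$total, r1$total)
})
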