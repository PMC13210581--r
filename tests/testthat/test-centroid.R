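test_that("Albers forward/inverse round-trips over the China window", {
  p <- albers_params()
  set.seed(14)
  lon <- runif(1000, 73, 135); lat <- runif(1000, 18, 54)
  xy <- albers_forward(lon, lat, p)
  ll <- albers_inverse(xy$x, xy$y, p)
  expect_lt(max(abs(ll$lon - lon)), 1e-9)
  expect_lt(max(abs(ll$lat - lat)), 1e-9)
  # central meridian maps to x = 0
  expect_equal(albers_forward(105, 33, p)$x, 0)
})

test_that("Albers preserves cell areas against the spherical band formula", {
  # projected quadrilateral area of each cell vs cell_areas, and the
  # grid total over a China-like window, within 0.5%
  spec <- grid_spec(36, 62, 73, 54, 1)
  a_sph <- cell_areas(spec)$values
  p <- albers_params()
  shoelace <- function(x, y) 0.5 * abs(sum(x * c(y[-1], y[1])) -
                                       sum(y * c(x[-1], x[1])))
  tot_alb <- 0
  for (r in seq(1, 36, by = 5)) for (cc in seq(1, 62, by = 10)) {
    w <- spec$lon_min + (cc - 1); n <- spec$lat_max - (r - 1)
    xy <- albers_forward(c(w, w + 1, w + 1, w), c(n, n, n - 1, n - 1), p)
    area_km2 <- shoelace(xy$x, xy$y) / 1e6
    expect_equal(area_km2, a_sph[r, cc], tolerance = 1e-3)
  }
  # whole-window totals
  xs <- lapply(seq_len(36), function(r) sapply(seq_len(62), function(cc) {
    w <- spec$lon_min + (cc - 1); n <- spec$lat_max - (r - 1)
    xy <- albers_forward(c(w, w + 1, w + 1, w), c(n, n, n - 1, n - 1), p)
    shoelace(xy$x, xy$y) / 1e6
  }))
  expect_equal(sum(unlist(xs)), sum(a_sph), tolerance = 5e-3)
})

test_that("weighted_centroid: single cell, symmetry, two-cell arithmetic", {
  spec <- grid_spec(5, 5, 102.5, 31.25, 1)  # central column on 105 E
  areas <- cell_areas(spec)
  one <- matrix(0, 5, 5); one[2, 4] <- 1
  cen <- weighted_centroid(raster_layer(spec, one, name = "m"), areas)
  expect_equal(cen$lon, cell_center_lon(spec, 4), tolerance = 1e-9)
  expect_equal(cen$lat, cell_center_lat(spec, 2), tolerance = 1e-9)

  # mask symmetric about the central column -> centroid lon = 105
  sym <- matrix(0, 5, 5); sym[3, c(1, 5)] <- 1; sym[2, c(2, 4)] <- 1
  cs <- weighted_centroid(raster_layer(spec, sym, name = "m"), areas)
  expect_equal(cs$lon, 105, tolerance = 1e-6)

  # two cells in one column: centroid is the area-weighted projected mean
  two <- matrix(0, 5, 5); two[1, 3] <- 1; two[5, 3] <- 1
  ct <- weighted_centroid(raster_layer(spec, two, name = "m"), areas)
  p <- albers_params()
  xy1 <- albers_forward(105, cell_center_lat(spec, 1), p)
  xy5 <- albers_forward(105, cell_center_lat(spec, 5), p)
  w1 <- areas$values[1, 3]; w5 <- areas$values[5, 3]
  want <- albers_inverse((xy1$x * w1 + xy5$x * w5) / (w1 + w5),
                         (xy1$y * w1 + xy5$y * w5) / (w1 + w5), p)
  expect_equal(ct$lat, want$lat, tolerance = 1e-9)
  expect_equal(ct$area_1e4km2, (w1 + w5) / 1e4, tolerance = 1e-12)

  expect_error(weighted_centroid(raster_layer(spec, matrix(0, 5, 5),
                                              name = "m"), areas),
               "no habitat")
})

test_that("centroids are insensitive to +/-2 degree Albers parameter shifts", {
  spec <- grid_spec(30, 30, 100, 33, 0.1)
  set.seed(6)
  blob <- matrix(0, 30, 30)
  blob[8:18, 10:20] <- rbinom(11 * 11, 1, 0.7)
  areas <- cell_areas(spec)
  msk <- raster_layer(spec, blob, name = "m")
  base <- weighted_centroid(msk, areas, albers_params())
  for (d in list(c(2, 0, 0), c(0, 2, 0), c(0, 0, -2))) {
    alt <- weighted_centroid(msk, areas,
                             albers_params(lon0 = 105 + d[1],
                                           lat1 = 25 + d[2],
                                           lat2 = 47 + d[3]))
    shift <- geodesic_distance_km(base$lon, base$lat, alt$lon, alt$lat)
    expect_lt(shift, 1)
  }
})

test_that("geodesic distance: exact cases, symmetry, triangle inequality", {
  expect_equal(geodesic_distance_km(105, 30, 105, 30), 0)
  # one degree along the equator = a * pi/180 exactly on the ellipsoid
  expect_equal(geodesic_distance_km(0, 0, 1, 0), 6378.137 * pi / 180,
               tolerance = 5e-4)
  expect_equal(geodesic_distance_km(0, 0, 1, 0), 111.319, tolerance = 5e-4)
  # due north: bearing 0, sector N
  g <- geodesic_inverse(105, 30, 105, 31)
  expect_equal(g$bearing_deg, 0, tolerance = 1e-9)
  expect_equal(bearing_sector(g$bearing_deg), "N")

  set.seed(10)
  for (i in 1:100) {
    a <- c(runif(1, 90, 120), runif(1, 18, 50))
    b <- c(runif(1, 90, 120), runif(1, 18, 50))
    cc <- c(runif(1, 90, 120), runif(1, 18, 50))
    dab <- geodesic_distance_km(a[1], a[2], b[1], b[2])
    dba <- geodesic_distance_km(b[1], b[2], a[1], a[2])
    expect_lt(abs(dab - dba), 1e-9)
    dac <- geodesic_distance_km(a[1], a[2], cc[1], cc[2])
    dcb <- geodesic_distance_km(cc[1], cc[2], b[1], b[2])
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("bearing sectors are total, deterministic and half-open", {
  expect_equal(bearing_sector(c(0, 90, 180, 225, 270)),
               c("N", "E", "S", "SW", "W"))
  expect_equal(bearing_sector(22.5), "NE")
  expect_equal(bearing_sector(22.49999), "N")
  expect_equal(bearing_sector(337.5), "N")
  expect_equal(bearing_sector(337.49), "NW")
  # total over a fine sweep
  sw <- bearing_sector(seq(0, 359.99, by = 0.01))
  expect_false(anyNA(sw))
  expect_error(bearing_sector(360))
})

test_that("shift_table: identity, southward translation, caveats, empty core", {
  spec <- grid_spec(40, 40, 100, 34, 0.1)
  areas <- cell_areas(spec)
  mk_cls <- function(vals, id) {
    m <- raster_layer(spec, vals, name = id)
    attr(m, "scenario_id") <- id
    class(m) <- c("classified_map", class(m))
    m
  }
  base_v <- matrix(0, 40, 40)
  base_v[10:20, 10:25] <- 1
  base_v[13:17, 14:20] <- 3
  cur <- mk_cls(base_v, "current")

  # identical future -> zero distance, "Original"
  tab_id <- shift_table(list(current = cur, same = mk_cls(base_v, "same")),
                        areas)
  expect_true(all(tab_id$distance_km[tab_id$scenario_id == "same"] < 1e-9))
  expect_equal(tab_id$sector[tab_id$scenario_id == "current"],
               c("Original", "Original"))

  # whole-pattern shift 8 rows south: both scopes land in sector S
  south_v <- matrix(0, 40, 40)
  south_v[18:28, 10:25] <- 1
  south_v[21:25, 14:20] <- 3
  tab_s <- shift_table(list(current = cur, fut = mk_cls(south_v, "fut")),
                       areas)
  fut <- tab_s[tab_s$scenario_id == "fut", ]
  expect_equal(fut$sector, c("S", "S"))
  expect_true(all(fut$distance_km > 5))

  # overall and core centroids can diverge: offset the high-class cells
  off_v <- base_v
  off_v[13:17, 14:20] <- 1
  off_v[10:12, 21:25] <- 3
  tab_o <- shift_table(list(current = mk_cls(off_v, "current")), areas)
  expect_gt(abs(tab_o$lon[1] - tab_o$lon[2]) +
            abs(tab_o$lat[1] - tab_o$lat[2]), 0.01)

  # small-area caveat: tiny core triggers the flag (floor 5 x 10^4 km^2)
  expect_true(all(tab_s$caveat[tab_s$scope == "core"]))

  # empty core produces a status row, not an error
  no_core <- base_v; no_core[no_core == 3] <- 2
  tab_e <- shift_table(list(current = cur, nc = mk_cls(no_core, "nc")), areas)
  erow <- tab_e[tab_e$scenario_id == "nc" & tab_e$scope == "core", ]
  expect_equal(erow$status, "no core habitat")
  expect_true(is.na(erow$lon))
})

test_that("centroid of a mask translated by whole cells moves accordingly", {
  spec <- grid_spec(30, 30, 100, 33, 0.1)
  areas <- cell_areas(spec)
  v <- matrix(0, 30, 30); v[5:10, 5:10] <- 1
  v2 <- matrix(0, 30, 30); v2[15:20, 5:10] <- 1  # 10 rows (1 degree) south
  c1 <- weighted_centroid(raster_layer(spec, v, name = "a"), areas)
  c2 <- weighted_centroid(raster_layer(spec, v2, name = "b"), areas)
  expect_equal(c2$lat, c1$lat - 1, tolerance = 0.01)      # 1% curvature tol
  expect_equal(c2$lon, c1$lon, tolerance = 0.01)
})
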