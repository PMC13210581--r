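#' Albers equal-area conic parameters
#'
#' Defaults are the common parameterization for China: central meridian
#' 105 E, standard parallels 25 N and 47 N, latitude of origin 0.
#' Projection equations are the standard spherical Albers forms on the
#' authalic sphere (R = 6371007.2 m).
#'
#' @param lon0 central meridian, degrees.
#' @param lat1,lat2 standard parallels, degrees.
#' @param lat0 latitude of origin, degrees.
#' @export
albers_params <- function(lon0 = 105, lat1 = 25, lat2 = 47, lat0 = 0) {
  structure(list(lon0 = lon0, lat1 = lat1, lat2 = lat2, lat0 = lat0,
                 R = 6371007.2),
            class = "albers_params")
}

#' Forward Albers equal-area conic projection (sphere)
#'
#' @param lon,lat coordinates in degrees.
#' @param params an [albers_params()].
#' @return list with `x`, `y` in meters.
#' @export
albers_forward <- function(lon, lat, params = albers_params()) {
  to_rad <- pi / 180
  p1 <- params$lat1 * to_rad; p2 <- params$lat2 * to_rad
  n <- (sin(p1) + sin(p2)) / 2
  C <- cos(p1)^2 + 2 * n * sin(p1)
  if (any(C - 2 * n * sin(lat * to_rad) < 0))
    stop("latitude outside the valid range of the cone")
  rho <- params$R / n * sqrt(C - 2 * n * sin(lat * to_rad))
  rho0 <- params$R / n * sqrt(C - 2 * n * sin(params$lat0 * to_rad))
  theta <- n * (lon - params$lon0) * to_rad
  list(x = rho * sin(theta), y = rho0 - rho * cos(theta))
}

#' Inverse Albers equal-area conic projection (sphere)
#'
#' @param x,y projected coordinates in meters.
#' @param params an [albers_params()].
#' @return list with `lon`, `lat` in degrees.
#' @export
albers_inverse <- function(x, y, params = albers_params()) {
  to_rad <- pi / 180
  p1 <- params$lat1 * to_rad; p2 <- params$lat2 * to_rad
  n <- (sin(p1) + sin(p2)) / 2
  C <- cos(p1)^2 + 2 * n * sin(p1)
  rho0 <- params$R / n * sqrt(C - 2 * n * sin(params$lat0 * to_rad))
  rho <- sqrt(x^2 + (rho0 - y)^2)
  theta <- atan2(x, rho0 - y)
  sin_lat <- (C - (rho * n / params$R)^2) / (2 * n)
  if (any(abs(sin_lat) > 1)) stop("point outside the valid cone range")
  list(lon = params$lon0 + theta / n / to_rad,
       lat = asin(sin_lat) / to_rad)
}

#' Area-weighted centroid of a habitat mask
#'
#' Projects every true cell's center to Albers, averages x and y weighted
#' by the cell's spherical area, and back-transforms the mean to WGS84.
#'
#' @param mask a 0/1 [raster_layer()] (1 = habitat).
#' @param areas matching [cell_areas()] layer.
#' @param params an [albers_params()].
#' @param scenario_id,scope labels recorded on the result.
#' @return a `centroid_record` list: `scenario_id`, `scope`, `lon`, `lat`,
#'   `area_1e4km2` (supporting area).
#' @export
weighted_centroid <- function(mask, areas, params = albers_params(),
                              scenario_id = "current", scope = "overall") {
  on <- which(mask$values == 1 & !mask$nodata_mask)
  if (!length(on)) stop("no habitat: the mask has no cells set")
  row <- ((on - 1L) %% mask$spec$n_rows) + 1L
  col <- ((on - 1L) %/% mask$spec$n_rows) + 1L
  lon <- cell_center_lon(mask$spec, col)
  lat <- cell_center_lat(mask$spec, row)
  w <- areas$values[on]
  xy <- albers_forward(lon, lat, params)
  ll <- albers_inverse(sum(xy$x * w) / sum(w), sum(xy$y * w) / sum(w), params)
  structure(list(scenario_id = scenario_id, scope = scope,
                 lon = ll$lon, lat = ll$lat,
                 area_1e4km2 = sum(w) / 1e4),
            class = "centroid_record")
}

#' Ellipsoidal geodesic between two points (Vincenty inverse)
#'
#' WGS84 ellipsoid (a = 6378.137 km, f = 1/298.257223563).  On the rare
#' antipodal non-convergence the spherical great-circle value is returned
#' with a warning.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return list with `distance_km` and `bearing_deg` (initial bearing at
#'   point 1, clockwise from north in `[0, 360)`).
#' @export
geodesic_inverse <- function(lon1, lat1, lon2, lat2) {
  a <- 6378.137; f <- 1 / 298.257223563; b <- a * (1 - f)
  to_rad <- pi / 180
  if (lon1 == lon2 && lat1 == lat2)
    return(list(distance_km = 0, bearing_deg = 0))
  U1 <- atan((1 - f) * tan(lat1 * to_rad))
  U2 <- atan((1 - f) * tan(lat2 * to_rad))
  L <- (lon2 - lon1) * to_rad
  sU1 <- sin(U1); cU1 <- cos(U1); sU2 <- sin(U2); cU2 <- cos(U2)
  lam <- L
  for (iter in 1:200) {
    sl <- sin(lam); cl <- cos(lam)
    sin_sigma <- sqrt((cU2 * sl)^2 + (cU1 * sU2 - sU1 * cU2 * cl)^2)
    if (sin_sigma == 0) return(list(distance_km = 0, bearing_deg = 0))
    cos_sigma <- sU1 * sU2 + cU1 * cU2 * cl
    sigma <- atan2(sin_sigma, cos_sigma)
    sin_alpha <- cU1 * cU2 * sl / sin_sigma
    cos2_alpha <- 1 - sin_alpha^2
    cos_2sm <- if (cos2_alpha == 0) 0 else cos_sigma - 2 * sU1 * sU2 / cos2_alpha
    Cc <- f / 16 * cos2_alpha * (4 + f * (4 - 3 * cos2_alpha))
    lam_new <- L + (1 - Cc) * f * sin_alpha *
      (sigma + Cc * sin_sigma * (cos_2sm + Cc * cos_sigma * (-1 + 2 * cos_2sm^2)))
    if (abs(lam_new - lam) < 1e-12) { lam <- lam_new; break }
    lam <- lam_new
    if (iter == 200) {
      warning("Vincenty did not converge (near-antipodal points); ",
              "falling back to the spherical great circle")
      d <- haversine_km(lon1, lat1, lon2, lat2)
      br <- spherical_bearing(lon1, lat1, lon2, lat2)
      return(list(distance_km = d, bearing_deg = br))
    }
  }
  sl <- sin(lam); cl <- cos(lam)
  sin_sigma <- sqrt((cU2 * sl)^2 + (cU1 * sU2 - sU1 * cU2 * cl)^2)
  cos_sigma <- sU1 * sU2 + cU1 * cU2 * cl
  sigma <- atan2(sin_sigma, cos_sigma)
  sin_alpha <- cU1 * cU2 * sl / sin_sigma
  cos2_alpha <- 1 - sin_alpha^2
  cos_2sm <- if (cos2_alpha == 0) 0 else cos_sigma - 2 * sU1 * sU2 / cos2_alpha
  u2 <- cos2_alpha * (a^2 - b^2) / b^2
  A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
  B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
  dsigma <- B * sin_sigma * (cos_2sm + B / 4 *
    (cos_sigma * (-1 + 2 * cos_2sm^2) -
     B / 6 * cos_2sm * (-3 + 4 * sin_sigma^2) * (-3 + 4 * cos_2sm^2)))
  dist <- b * A * (sigma - dsigma)
  bearing <- atan2(cU2 * sl, cU1 * sU2 - sU1 * cU2 * cl) / to_rad
  list(distance_km = dist, bearing_deg = (bearing + 360) %% 360)
}

spherical_bearing <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dl <- (lon2 - lon1) * to_rad
  y <- sin(dl) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dl)
  (atan2(y, x) / to_rad + 360) %% 360
}

#' Geodesic distance in km
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @export
geodesic_distance_km <- function(lon1, lat1, lon2, lat2)
  geodesic_inverse(lon1, lat1, lon2, lat2)$distance_km

#' Initial bearing in degrees clockwise from north
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @export
initial_bearing_deg <- function(lon1, lat1, lon2, lat2)
  geodesic_inverse(lon1, lat1, lon2, lat2)$bearing_deg

#' Map a bearing to one of eight compass sectors
#'
#' 45-degree sectors centered on the cardinal/intercardinal directions:
#' N covers `[337.5, 360) U [0, 22.5)`, NE `[22.5, 67.5)`, and so on
#' (half-open on the right).
#'
#' @param bearing_deg bearing(s) in `[0, 360)`.
#' @return character sector(s) in N/NE/E/SE/S/SW/W/NW.
#' @export
bearing_sector <- function(bearing_deg) {
  stopifnot(all(bearing_deg >= 0 & bearing_deg < 360))
  sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  sectors[floor(((bearing_deg + 22.5) %% 360) / 45) + 1]
}

#' Centroid-shift table across scenarios
#'
#' For each scenario and for both habitat scopes — overall (classes 1-3)
#' and core (class 3 only) — computes the area-weighted centroid, then the
#' geodesic distance, initial bearing and compass sector from the current
#' centroid.  The current row gets direction "Original".  A scenario whose
#' supporting area falls below `area_floor` (10^4 km^2) is flagged with a
#' small-area caveat; an empty core yields a "no core habitat" status row.
#'
#' @param classified_maps named list of [classify_map()] results; the
#'   first entry is the current/baseline scenario.
#' @param areas matching [cell_areas()] layer.
#' @param params an [albers_params()].
#' @param area_floor caveat threshold in 10^4 km^2 (default 5).
#' @return data.frame with `scenario_id`, `scope`, `lon`, `lat`,
#'   `distance_km`, `bearing_deg`, `sector`, `area_1e4km2`, `caveat`,
#'   `status`.
#' @export
shift_table <- function(classified_maps, areas, params = albers_params(),
                        area_floor = 5) {
  stopifnot(length(classified_maps) >= 1)
  ids <- names(classified_maps) %||%
    vapply(classified_maps, function(m)
      attr(m, "scenario_id") %||% "scenario", character(1))
  scope_mask <- function(m, scope) {
    v <- if (scope == "overall") (m$values >= 1) * 1 else (m$values == 3) * 1
    raster_layer(m$spec, v, m$nodata_mask, name = scope)
  }
  rows <- list()
  for (scope in c("overall", "core")) {
    base_cen <- weighted_centroid(scope_mask(classified_maps[[1]], scope),
                                  areas, params, ids[1], scope)
    for (i in seq_along(classified_maps)) {
      msk <- scope_mask(classified_maps[[i]], scope)
      if (!any(msk$values == 1 & !msk$nodata_mask)) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario_id = ids[i], scope = scope, lon = NA_real_, lat = NA_real_,
          distance_km = NA_real_, bearing_deg = NA_real_, sector = NA_character_,
          area_1e4km2 = 0, caveat = TRUE, status = "no core habitat",
          stringsAsFactors = FALSE)
        next
      }
      cen <- weighted_centroid(msk, areas, params, ids[i], scope)
      if (i == 1) {
        d <- 0; br <- NA_real_; sec <- "Original"
      } else {
        g <- geodesic_inverse(base_cen$lon, base_cen$lat, cen$lon, cen$lat)
        d <- g$distance_km; br <- g$bearing_deg
        sec <- if (d == 0) "Original" else bearing_sector(br)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_id = ids[i], scope = scope, lon = cen$lon, lat = cen$lat,
        distance_km = d, bearing_deg = br, sector = sec,
        area_1e4km2 = cen$area_1e4km2,
        caveat = cen$area_1e4km2 < area_floor, status = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
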