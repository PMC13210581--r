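#' Regular longitude/latitude grid specification
#'
#' Describes a north-up grid of square cells in geographic (WGS84)
#' coordinates.  Row 1 is the northernmost row; `lon_min`/`lat_max` are the
#' *outer edges* of the top-left cell.  Cell centers sit at
#' `edge + (i - 0.5) * cell_size`.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param lon_min western edge of the grid, degrees.
#' @param lat_max northern edge of the grid, degrees.
#' @param cell_size cell edge length in degrees (> 0); cells are square.
#' @param crs_id coordinate system label; always geographic WGS84.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, lon_min, lat_max, cell_size,
                      crs_id = "WGS84") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  if (lat_max - n_rows * cell_size < -90 - 1e-9)
    stop("grid extends below -90 degrees latitude")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 lon_min = as.numeric(lon_min), lat_max = as.numeric(lat_max),
                 cell_size = as.numeric(cell_size), crs_id = crs_id),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g deg, lon [%g, %g], lat [%g, %g]\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$lon_min, x$lon_min + x$n_cols * x$cell_size,
              x$lat_max - x$n_rows * x$cell_size, x$lat_max))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lat_max - b$lat_max) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Longitudes of cell centers for given columns
#' @param spec a [grid_spec()].
#' @param col column indices (1-based).
#' @export
cell_center_lon <- function(spec, col) spec$lon_min + (col - 0.5) * spec$cell_size

#' Latitudes of cell centers for given rows
#' @param spec a [grid_spec()].
#' @param row row indices (1-based, row 1 = north).
#' @export
cell_center_lat <- function(spec, row) spec$lat_max - (row - 0.5) * spec$cell_size

#' Locate the cell containing each point
#'
#' Cells are half-open intervals `[edge, edge + size)` in longitude and
#' `(edge - size, edge]` going south in latitude, i.e. a point on a shared
#' edge belongs to its east/south neighbour, and points on the max-lon or
#' min-lat outer edge fall outside the grid.
#'
#' @param spec a [grid_spec()].
#' @param lon,lat point coordinates, degrees.
#' @return data.frame with columns `row`, `col` (NA outside) and `inside`.
#' @export
lonlat_to_cell <- function(spec, lon, lat) {
  col <- floor((lon - spec$lon_min) / spec$cell_size) + 1
  row <- floor((spec$lat_max - lat) / spec$cell_size) + 1
  ## a point exactly on the northern outer edge belongs to row 1
  row[!is.na(lat) & lat == spec$lat_max] <- 1
  inside <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= spec$n_rows & col >= 1 & col <= spec$n_cols
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Single-band raster on a regular lon/lat grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix `n_rows x n_cols`, row 1 = north.
#' @param nodata_mask logical matrix of the same shape; `TRUE` marks cells
#'   with no data.  Values must be finite wherever the mask is `FALSE`.
#' @param name layer name, e.g. `"bio7"` or `"elev"`.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(spec, values, nodata_mask = NULL, name = "layer") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop("values shape does not match grid spec")
  if (is.null(nodata_mask))
    nodata_mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
  nodata_mask <- as.matrix(nodata_mask)
  if (!all(dim(nodata_mask) == dim(values)))
    stop("nodata_mask shape does not match values")
  if (any(!is.finite(values[!nodata_mask])))
    stop("non-finite values outside the nodata mask")
  structure(list(spec = spec, values = values,
                 nodata_mask = nodata_mask, name = name),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<raster_layer> '%s' %dx%d, %d nodata, range [%g, %g]\n",
              x$name, x$spec$n_rows, x$spec$n_cols, sum(x$nodata_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Ordered stack of co-registered predictor layers
#'
#' @param layers list of [raster_layer()] objects sharing one grid.
#' @param scenario_id scenario label, e.g. `"current"` or `"SSP126-2050s"`.
#' @return an object of class `predictor_stack`.  The union of the layers'
#'   nodata masks defines the stack's valid cells.
#' @export
predictor_stack <- function(layers, scenario_id = "current") {
  stopifnot(length(layers) >= 1)
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  spec <- layers[[1]]$spec
  for (l in layers) {
    if (!inherits(l, "raster_layer")) stop("layers must be raster_layer objects")
    if (!same_grid(spec, l$spec)) stop("grid mismatch between stacked layers")
  }
  mask <- Reduce(`|`, lapply(layers, function(l) l$nodata_mask))
  names(layers) <- nm
  structure(list(layers = layers, spec = spec, scenario_id = scenario_id,
                 nodata_mask = mask),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> '%s': %d layers (%s) on %dx%d grid\n",
              x$scenario_id, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

#' Per-cell area of a lon/lat grid
#'
#' Exact spherical band areas on the authalic sphere (R = 6371.0072 km):
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`.  Areas depend on
#' the row only.
#'
#' @param spec a [grid_spec()].
#' @return a [raster_layer()] named `"cell_area_km2"` with km^2 per cell.
#' @export
cell_areas <- function(spec) {
  R <- 6371.0072
  lat_top <- spec$lat_max - (seq_len(spec$n_rows) - 1) * spec$cell_size
  lat_bot <- lat_top - spec$cell_size
  dl <- spec$cell_size * pi / 180
  row_area <- R^2 * dl * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  raster_layer(spec, matrix(row_area, spec$n_rows, spec$n_cols),
               name = "cell_area_km2")
}

#' Extract per-layer values at points
#'
#' Containing-cell lookup under the half-open cell convention of
#' [lonlat_to_cell()].  Points outside the grid or on masked cells are
#' flagged invalid rather than raising an error.
#'
#' @param stack a [predictor_stack()].
#' @param lon,lat point coordinates, degrees.
#' @return data.frame with one column per layer plus `row`, `col`, `valid`.
#' @export
extract_values <- function(stack, lon, lat) {
  cells <- lonlat_to_cell(stack$spec, lon, lat)
  n <- nrow(cells)
  out <- cells[, c("row", "col")]
  idx <- ifelse(cells$inside, (cells$col - 1L) * stack$spec$n_rows + cells$row, NA)
  masked <- rep(TRUE, n)
  masked[cells$inside] <- stack$nodata_mask[idx[cells$inside]]
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, n)
    ok <- cells$inside & !masked
    v[ok] <- stack$layers[[nm]]$values[idx[ok]]
    out[[nm]] <- v
  }
  out$valid <- cells$inside & !masked
  out
}
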