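#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band georeferenced format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header, then rows north to south).
#' Values are printed with 17 significant digits so doubles round-trip
#' bit-for-bit; integer layers (e.g. 0-1000 suitability maps) round-trip
#' exactly.
#'
#' @param layer a [raster_layer()].
#' @param path output file path (`.asc`); parent directory must exist.
#' @param nodata numeric sentinel written at masked cells (default -9999;
#'   integer suitability maps conventionally use -1).
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "raster_layer"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  s <- layer$spec
  v <- layer$values
  v[layer$nodata_mask] <- nodata
  yll <- s$lat_max - s$n_rows * s$cell_size
  hdr <- c(sprintf("ncols %d", s$n_cols),
           sprintf("nrows %d", s$n_rows),
           sprintf("xllcorner %.17g", s$lon_min),
           sprintf("yllcorner %.17g", yll),
           sprintf("cellsize %.17g", s$cell_size),
           sprintf("NODATA_value %.17g", nodata))
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file path.
#' @param name layer name; defaults to the file name without extension.
#' @return a [raster_layer()]; the file's nodata value becomes the mask.
#'   `xllcenter`-registered or non-square-cell (`dx`/`dy`) files are
#'   rejected with an explicit grid-mismatch message.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value", "dx", "dy")) {
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("grid mismatch: non-square-cell (dx/dy) rasters are not supported")
  if (!is.null(hdr$xllcenter) || !is.null(hdr$yllcenter))
    stop("grid mismatch: center-registered rasters are not supported")
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, found ", length(vals), " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m == nodata
  m[mask] <- NA_real_
  m[mask] <- 0  # placeholder under the mask; never read
  spec <- grid_spec(nr, nc, hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                    hdr$cellsize)
  raster_layer(spec, m, mask,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a predictor stack as per-layer ASCII grids plus a JSON manifest
#'
#' @param stack a [predictor_stack()].
#' @param dir output directory (created if needed).
#' @param extra named list merged into the manifest (seed, generator
#'   parameters, ...).
#' @export
write_stack <- function(stack, dir, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(stack$layers)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    write_raster(stack$layers[[nm]], f)
    files <- c(files, basename(f))
  }
  manifest <- c(list(scenario_id = stack$scenario_id,
                     layer_order = names(stack$layers), files = files),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a predictor stack written by [write_stack()]
#' @param dir directory containing `stack.json` and the `.asc` layers.
#' @export
read_stack <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- lapply(seq_along(mf$layer_order), function(i)
    read_raster(file.path(dir, mf$files[i]), name = mf$layer_order[i]))
  predictor_stack(layers, scenario_id = mf$scenario_id)
}
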