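#' Occurrence table constructor
#'
#' A thin data.frame subclass carrying presence records and their cleaning
#' audit trail.  Optional fields that are absent in the source data stay
#' `NA` (never imputed).  `status` is one of `"raw"`, `"retained"`,
#' `"dropped"`; `drop_reason` is set exactly when a record is dropped.
#' `truth_tag` is reserved for the synthetic generator's planted-violation
#' labels and is ignored by the cleaning pipeline.
#'
#' @param id character record ids (unique).
#' @param lon,lat coordinates in degrees (NA allowed; cleaned later).
#' @param precision_deg,year,elevation_m optional per-record metadata.
#' @param sea_flag,centroid_flag,institution_flag provenance booleans from
#'   upstream gazetteer checks.
#' @param truth_tag synthetic contamination label or NA.
#' @return an object of classes `occurrence_table` and `data.frame`.
#' @export
occurrence_table <- function(id, lon, lat,
                             precision_deg = NA_real_, year = NA_integer_,
                             elevation_m = NA_real_, sea_flag = FALSE,
                             centroid_flag = FALSE, institution_flag = FALSE,
                             truth_tag = NA_character_) {
  n <- length(id)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate occurrence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  df <- data.frame(id = id, lon = as.numeric(lon), lat = as.numeric(lat),
                   precision_deg = rep_len(as.numeric(precision_deg), n),
                   year = rep_len(as.integer(year), n),
                   elevation_m = rep_len(as.numeric(elevation_m), n),
                   sea_flag = rep_len(as.logical(sea_flag), n),
                   centroid_flag = rep_len(as.logical(centroid_flag), n),
                   institution_flag = rep_len(as.logical(institution_flag), n),
                   truth_tag = rep_len(as.character(truth_tag), n),
                   status = rep("raw", n),
                   drop_reason = rep(NA_character_, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("occurrence_table", "data.frame")
  df
}

num_or_na <- function(x, what, rows) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad))
    stop("unparseable ", what, " at row(s) ",
         paste(rows[bad], collapse = ", "))
  out
}

#' Read occurrence records from a delimited text file
#'
#' Expects a header with at least `id`, `lon`, `lat`; the optional columns
#' `precision_deg`, `year`, `elevation_m`, `sea_flag`, `centroid_flag`,
#' `institution_flag` and `truth_tag` are picked up when present and left
#' absent (NA) otherwise.  Duplicate ids and unparseable coordinates are
#' errors reporting the offending ids / row numbers.
#'
#' @param path CSV file path.
#' @return an [occurrence_table()] with all records in status `"raw"`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat")
  if (!all(need %in% names(raw)))
    stop("occurrence file must have columns id, lon, lat")
  rows <- seq_len(nrow(raw)) + 1L  # header is line 1
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NA
  as_flag <- function(x) {
    x <- tolower(trimws(as.character(x)))
    !is.na(x) & x %in% c("true", "t", "1", "yes")
  }
  occurrence_table(
    id = raw$id,
    lon = num_or_na(raw$lon, "lon", rows),
    lat = num_or_na(raw$lat, "lat", rows),
    precision_deg = num_or_na(grab("precision_deg"), "precision_deg", rows),
    year = num_or_na(grab("year"), "year", rows),
    elevation_m = num_or_na(grab("elevation_m"), "elevation_m", rows),
    sea_flag = as_flag(grab("sea_flag")),
    centroid_flag = as_flag(grab("centroid_flag")),
    institution_flag = as_flag(grab("institution_flag")),
    truth_tag = as.character(grab("truth_tag")))
}

#' Write an occurrence table to CSV
#' @param occ an [occurrence_table()].
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, na = "")
  invisible(path)
}
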