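#' Binarize a suitability map at a cutoff
#'
#' A cell is suitable iff its value exceeds the cutoff; nodata preserved.
#'
#' @param map an integer 0-1000 suitability [raster_layer()].
#' @param cutoff integer in 0..999.
#' @return a 0/1 [raster_layer()].
#' @export
binarize <- function(map, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 999)
  v <- (map$values > cutoff) * 1
  v[map$nodata_mask] <- 0
  raster_layer(map$spec, v, map$nodata_mask,
               name = paste0(map$name, "_bin"))
}

#' Jenks natural breaks (exact Fisher optimal partition)
#'
#' Exact dynamic program minimizing the total within-class sum of squared
#' deviations over ordered partitions.  Values are first collapsed to
#' (value, count) pairs, so integer suitability rasters with up to 1001
#' distinct values stay fast.  Breaks are reported as the maximum value of
#' each class except the last.
#'
#' @param values numeric multiset (|values| >= k).
#' @param k number of classes (>= 2).
#' @return numeric vector of k - 1 break values, with the minimized SSE
#'   attached as attribute `"sse"`.  Fewer distinct values than k yields
#'   degenerate breaks with a warning.
#' @export
jenks_breaks <- function(values, k) {
  values <- values[!is.na(values)]
  stopifnot(k >= 2, length(values) >= k)
  tab <- table(values)
  v <- as.numeric(names(tab))
  w <- as.numeric(tab)
  n <- length(v)
  if (n < k) {
    warning("fewer distinct values (", n, ") than classes (", k,
            "); returning degenerate breaks")
    return(structure(c(v[seq_len(n - 1)], rep(v[n], k - n)), sse = 0))
  }
  ## prefix sums for O(1) weighted SSE of any run v[a..b]
  cw <- c(0, cumsum(w)); cwv <- c(0, cumsum(w * v)); cwv2 <- c(0, cumsum(w * v^2))
  sse_run <- function(a, b) {
    W <- cw[b + 1] - cw[a]; S <- cwv[b + 1] - cwv[a]; Q <- cwv2[b + 1] - cwv2[a]
    pmax(Q - S^2 / W, 0)
  }
  ## D[m, i] = minimal SSE of splitting v[1..i] into m classes
  D <- matrix(Inf, k, n)
  D[1, ] <- sse_run(1, seq_len(n))
  idx <- matrix(0L, k, n)
  for (m in 2:k) {
    for (i in m:n) {
      j <- m:i  # first index of the last class
      cand <- D[m - 1, j - 1] + sse_run(j, i)
      best <- which.min(cand)
      D[m, i] <- cand[best]
      idx[m, i] <- j[best]
    }
  }
  ## backtrack class boundaries
  breaks <- numeric(k - 1)
  i <- n
  for (m in k:2) {
    j <- idx[m, i]
    breaks[m - 1] <- v[j - 1]  # max value of the class ending at j-1
    i <- j - 1
  }
  structure(breaks, sse = D[k, n])
}

#' Class break container
#'
#' Four classes on the 0-1000 scale: unsuitable `[0, cutoff]`, low
#' `(cutoff, b1]`, moderate `(b1, b2]`, high `(b2, 1000]`.
#'
#' @param cutoff the binarization cutoff.
#' @param b1,b2 interior breaks with `cutoff < b1 < b2 < 1000`.
#' @param provenance `"jenks-on-baseline"` or `"explicit"`.
#' @export
class_breaks <- function(cutoff, b1, b2, provenance = "explicit") {
  if (!(cutoff < b1 && b1 < b2 && b2 < 1000))
    stop("breaks must satisfy cutoff < b1 < b2 < 1000")
  structure(list(cutoff = cutoff, b1 = b1, b2 = b2, provenance = provenance),
            class = "class_breaks")
}

#' Cutoff-anchored Jenks classification of the baseline map
#'
#' Jenks breaks are computed on the multiset of baseline *suitable* cell
#' values (value > cutoff) with `k_suitable` classes, so the unsuitable
#' class ends exactly at the binarization cutoff; the same breaks are then
#' reused for every scenario.  Explicit breaks bypass Jenks.
#'
#' @param baseline the baseline suitability map.
#' @param cutoff binarization cutoff (TSS-maximizing by construction).
#' @param k_suitable suitable classes (default 3: low/moderate/high).
#' @param explicit optional `c(b1, b2)` supplied by configuration.
#' @return a [class_breaks()] object.
#' @export
anchored_classification <- function(baseline, cutoff, k_suitable = 3,
                                    explicit = NULL) {
  if (!is.null(explicit))
    return(class_breaks(cutoff, explicit[1], explicit[2], "explicit"))
  vals <- baseline$values[!baseline$nodata_mask]
  vals <- vals[vals > cutoff]
  if (length(vals) < k_suitable) stop("fewer suitable cells than classes")
  br <- jenks_breaks(vals, k_suitable)
  class_breaks(cutoff, br[1], br[2], "jenks-on-baseline")
}

#' Classify a suitability map into 4 habitat classes
#'
#' Class 0 (unsuitable) iff value <= cutoff; 1 (low) in `(cutoff, b1]`;
#' 2 (moderate) in `(b1, b2]`; 3 (high) above `b2`.
#'
#' @param map a suitability [raster_layer()].
#' @param breaks a [class_breaks()] object.
#' @return a `classified_map`: raster of classes 0-3 with breaks attached.
#' @export
classify_map <- function(map, breaks) {
  stopifnot(inherits(breaks, "class_breaks"))
  v <- map$values
  cl <- (v > breaks$cutoff) + (v > breaks$b1) + (v > breaks$b2)
  cl[map$nodata_mask] <- 0
  out <- raster_layer(map$spec, cl, map$nodata_mask,
                      name = paste0(map$name, "_class"))
  attr(out, "breaks") <- breaks
  attr(out, "scenario_id") <- attr(map, "scenario_id")
  class(out) <- c("classified_map", class(out))
  out
}

habitat_class_names <- c("unsuitable", "low", "moderate", "high")

#' Equal-area class-area table
#'
#' Sums per-cell spherical areas by class; areas reported in 10^4 km^2,
#' proportions in percent of the total valid-cell area.  The total
#' suitable row is low + moderate + high.
#'
#' @param classified a [classify_map()] result.
#' @param areas matching [cell_areas()] layer.
#' @return an `area_table` data.frame (`class`, `area_1e4km2`,
#'   `proportion_pct`) with a `total_suitable` row and `scenario_id`
#'   attribute.
#' @export
area_table <- function(classified, areas) {
  if (!same_grid(classified$spec, areas$spec)) stop("grid mismatch")
  valid <- !classified$nodata_mask
  a <- vapply(0:3, function(k)
    sum(areas$values[valid & classified$values == k]) / 1e4, numeric(1))
  make_area_table(a[1], a[2], a[3], a[4],
                  scenario_id = attr(classified, "scenario_id") %||% "current")
}

#' Assemble an area table from known class areas
#'
#' Useful for recomputing published area statistics: supply the four
#' class areas directly (in 10^4 km^2) and get proportions and the total
#' suitable row.
#'
#' @param unsuitable,low,moderate,high class areas, 10^4 km^2.
#' @param scenario_id scenario label.
#' @export
make_area_table <- function(unsuitable, low, moderate, high,
                            scenario_id = "current") {
  a <- c(unsuitable, low, moderate, high)
  total <- sum(a)
  out <- data.frame(class = c(habitat_class_names, "total_suitable"),
                    area_1e4km2 = c(a, sum(a[2:4])),
                    proportion_pct = 100 * c(a, sum(a[2:4])) / total,
                    stringsAsFactors = FALSE)
  attr(out, "scenario_id") <- scenario_id
  class(out) <- c("area_table", "data.frame")
  out
}

#' Look up one class area in an area table
#' @param tbl an [area_table()] result.
#' @param cls class name (`"unsuitable"`, `"low"`, `"moderate"`, `"high"`,
#'   `"total_suitable"`).
#' @return the class area in 10^4 km^2.
#' @export
area_of <- function(tbl, cls) tbl$area_1e4km2[tbl$class == cls]

#' Change statistics between two area tables
#'
#' Per-class area change and rate relative to the current table, plus the
#' two headline rates: total suitable habitat and high-suitability core
#' habitat, each `100 * (future - current) / current`.
#'
#' @param current,future [area_table()] objects on the same breaks.
#' @return a `change_record` list: `scenario_id`, per-class `change` and
#'   `rate_pct`, `rate_total_pct`, `rate_core_pct`.
#' @export
change_stats <- function(current, future) {
  stopifnot(inherits(current, "area_table"), inherits(future, "area_table"))
  if (area_of(current, "total_suitable") <= 0)
    stop("current total suitable area must be positive")
  classes <- c(habitat_class_names, "total_suitable")
  cur <- vapply(classes, function(k) area_of(current, k), numeric(1))
  fut <- vapply(classes, function(k) area_of(future, k), numeric(1))
  rate <- ifelse(cur > 0, 100 * (fut - cur) / cur, NA_real_)
  structure(list(scenario_id = attr(future, "scenario_id"),
                 change = fut - cur, rate_pct = rate,
                 rate_total_pct = rate[["total_suitable"]],
                 rate_core_pct = rate[["high"]]),
            class = "change_record")
}
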