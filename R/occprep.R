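#' Cleaning rules for occurrence records
#'
#' Defaults follow common practice for presence records feeding a
#' 2.5-arc-minute SDM: coordinate precision no coarser than 0.01 degrees,
#' elevation within 200-2200 m, collection year 1970 or later (matching
#' the baseline climatology), and a bounding-box study domain.
#'
#' @param max_precision_deg coarsest acceptable coordinate precision.
#' @param elev_range acceptable elevation range in meters, `c(min, max)`.
#' @param min_year earliest acceptable collection year.
#' @param domain study domain as `c(lon_min, lon_max, lat_min, lat_max)`
#'   or NULL to skip the domain rule.
#' @param flag_rules apply the sea/centroid/institution flag rule.
#' @param strict in strict mode (default) records missing a field that a
#'   rule needs are dropped with reason `"missing-field"`; in lenient mode
#'   such rules pass.
#' @export
cleaning_rules <- function(max_precision_deg = 0.01,
                           elev_range = c(200, 2200),
                           min_year = 1970, domain = NULL,
                           flag_rules = TRUE, strict = TRUE) {
  stopifnot(max_precision_deg > 0, elev_range[1] < elev_range[2])
  structure(list(max_precision_deg = max_precision_deg,
                 elev_range = elev_range, min_year = min_year,
                 domain = domain, flag_rules = flag_rules, strict = strict),
            class = "cleaning_rules")
}

#' Clean raw occurrence records
#'
#' Applies, in fixed order: (1) missing coordinates; (2) coordinate
#' precision coarser than the threshold; (3) sea/centroid/institution
#' flags; (4) equal longitude and latitude or zero coordinates;
#' (5) outside the study domain; (6) elevation outside range; (7) year
#' before the minimum.  Only the first failing rule is recorded as the
#' drop reason, so the audit is deterministic.
#'
#' @param raw an [occurrence_table()] with records in status `"raw"`.
#' @param rules a [cleaning_rules()].
#' @return the table with statuses set; the audit summary (named drop
#'   counts plus `retained`) is attached as attribute `"audit"`.
#' @export
clean_records <- function(raw, rules = cleaning_rules()) {
  stopifnot(inherits(raw, "occurrence_table"))
  if (!all(raw$status == "raw")) stop("records must be in status 'raw'")
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  need <- function(x, test) {
    ## strict mode: a rule that needs an absent field drops the record
    out <- ifelse(is.na(x), if (rules$strict) "missing-field" else NA,
                  ifelse(test, "fail", NA))
    out
  }
  set_reason <- function(reason, verdict, rule_name) {
    hit <- is.na(reason) & !is.na(verdict)
    reason[hit] <- ifelse(verdict[hit] == "fail", rule_name, "missing-field")
    reason
  }
  ## (1) missing coordinates
  reason[is.na(raw$lon) | is.na(raw$lat)] <- "missing-coords"
  ## (2) precision
  reason <- set_reason(reason, need(raw$precision_deg,
                                    raw$precision_deg > rules$max_precision_deg),
                       "precision")
  ## (3) provenance flags
  if (rules$flag_rules) {
    flagged <- raw$sea_flag | raw$centroid_flag | raw$institution_flag
    hit <- is.na(reason) & !is.na(flagged) & flagged
    reason[hit] <- "flag"
  }
  ## (4) degenerate coordinates
  degen <- raw$lon == raw$lat | raw$lon == 0 | raw$lat == 0
  hit <- is.na(reason) & !is.na(degen) & degen
  reason[hit] <- "equal-coords"
  ## (5) domain
  if (!is.null(rules$domain)) {
    d <- rules$domain
    outside <- raw$lon < d[1] | raw$lon > d[2] | raw$lat < d[3] | raw$lat > d[4]
    hit <- is.na(reason) & !is.na(outside) & outside
    reason[hit] <- "domain"
  }
  ## (6) elevation
  reason <- set_reason(reason, need(raw$elevation_m,
                                    raw$elevation_m < rules$elev_range[1] |
                                    raw$elevation_m > rules$elev_range[2]),
                       "elevation")
  ## (7) year
  reason <- set_reason(reason, need(raw$year, raw$year < rules$min_year),
                       "year")

  out <- raw
  out$status <- ifelse(is.na(reason), "retained", "dropped")
  out$drop_reason <- reason
  attr(out, "audit") <- audit_summary(out, n)
  out
}

audit_summary <- function(tab, n_input) {
  drops <- table(tab$drop_reason[tab$status == "dropped"])
  c(as.list(drops), list(retained = sum(tab$status == "retained"),
                         input = n_input))
}

#' Spatially thin retained records to one per grid cell
#'
#' Exact cell binning: within each occupied cell the record with the
#' lexicographically smallest id is kept; the rest are dropped with reason
#' `"thinned"`.  The tie rule makes thinning idempotent and independent of
#' input row order.
#'
#' @param cleaned an [occurrence_table()]; only retained records are
#'   considered (others pass through untouched).
#' @param spec the [grid_spec()] defining the thinning resolution.
#' @export
thin_records <- function(cleaned, spec) {
  stopifnot(inherits(cleaned, "occurrence_table"), inherits(spec, "grid_spec"))
  out <- cleaned
  keep_i <- which(out$status == "retained")
  if (!length(keep_i)) return(out)
  cells <- lonlat_to_cell(spec, out$lon[keep_i], out$lat[keep_i])
  key <- paste(cells$row, cells$col, sep = ":")
  key[!cells$inside] <- paste0("outside:", out$id[keep_i][!cells$inside])
  ord <- order(key, out$id[keep_i], method = "radix")
  dup <- duplicated(key[ord])
  dropped <- keep_i[ord][dup]
  out$status[dropped] <- "dropped"
  out$drop_reason[dropped] <- "thinned"
  attr(out, "audit") <- audit_summary(out, nrow(out))
  out
}

#' Drop records that fall on masked or out-of-grid cells
#'
#' @param thinned an [occurrence_table()].
#' @param stack the [predictor_stack()] the records must be valid on.
#' @return the table with invalid records dropped, reason `"no-data-cell"`.
#' @export
validate_on_stack <- function(thinned, stack) {
  stopifnot(inherits(thinned, "occurrence_table"))
  out <- thinned
  keep_i <- which(out$status == "retained")
  if (!length(keep_i)) return(out)
  ex <- extract_values(stack, out$lon[keep_i], out$lat[keep_i])
  bad <- keep_i[!ex$valid]
  out$status[bad] <- "dropped"
  out$drop_reason[bad] <- "no-data-cell"
  attr(out, "audit") <- audit_summary(out, nrow(out))
  out
}

#' Retained records of an occurrence table
#' @param occ an [occurrence_table()].
#' @export
retained_records <- function(occ) {
  out <- occ[occ$status == "retained", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid cells occupied by the retained records
#' @param occ an [occurrence_table()] (retained records used).
#' @param spec a [grid_spec()].
#' @return data.frame with `row`, `col`, one per record.
#' @export
presence_cells <- function(occ, spec) {
  r <- retained_records(occ)
  cells <- lonlat_to_cell(spec, r$lon, r$lat)
  if (any(!cells$inside)) stop("retained records outside the grid")
  cells[, c("row", "col")]
}
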