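#' Build a validated run configuration
#'
#' Single configuration object with every stage parameter and its default;
#' unknown keys are rejected so typos cannot silently fall back to
#' defaults.  The defaults describe the synthetic world the pipeline is
#' exercised on: a 150 x 150 grid of six standardized predictor layers
#' (four signal + two decoys), 200 genuine presences, and the screening /
#' ensemble thresholds of the standard protocol (|r| >= 0.80, VIF > 10,
#' TSS gate 0.70, 3 x 5 replicate design, 10,000 pseudo-absences per set).
#'
#' @param ... overrides of the defaults listed in the function definition.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    out_dir = "ensdm-run",
    seed = 123,
    n_rows = 150, n_cols = 150,
    lon_min = 97, lat_max = 34, cell_size = 0.1,
    n_layers = 6, corr_length = 8,
    n_occurrences = 200,
    contaminate = TRUE,
    r_cutoff = 0.80, vif_threshold = 10,
    n_background = 10000,
    n_pa = 10000, n_sets = 3, buffer_km = 5,
    frac = 0.75, n_repeats = 5,
    tss_gate = 0.70,
    n_perm = 10,
    k_suitable = 3,
    area_floor = 5,
    learners = c("glm_quad", "ridge", "gam", "fda", "sre"),
    albers = list(lon0 = 105, lat1 = 25, lat2 = 47, lat0 = 0))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$frac > 0, cfg$frac < 1, cfg$tss_gate >= -1, cfg$tss_gate <= 1,
            cfg$r_cutoff > 0, cfg$r_cutoff <= 1, cfg$vif_threshold > 1,
            cfg$n_sets >= 1, cfg$n_repeats >= 1)
  structure(cfg, class = "run_config")
}

make_learners <- function(names) {
  all <- list(glm_quad = learner_glm_quad, ridge = learner_ridge,
              gam = learner_gam, fda = learner_fda, sre = learner_sre)
  unknown <- setdiff(names, names(all))
  if (length(unknown)) stop("unknown learner(s): ",
                            paste(unknown, collapse = ", "))
  lapply(names, function(n) all[[n]]())
}

cfg_spec <- function(cfg) grid_spec(cfg$n_rows, cfg$n_cols, cfg$lon_min,
                                    cfg$lat_max, cfg$cell_size)
cfg_albers <- function(cfg) do.call(albers_params, cfg$albers)

artifact <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing upstream artifact: ", path)
  path
}

#' Run the pipeline
#'
#' Orchestrates the stages `simulate` (synthetic stacks, truth and
#' occurrences), `prep` (clean/thin/validate), `screen` (collinearity
#' screening), `fit` (replicate models), `evaluate`, `ensemble`,
#' `project`, `classify`, `centroids` and `report`, writing each stage's
#' artifacts plus a manifest under `cfg$out_dir`.  `stage = "all"` runs
#' everything in order; a later stage run on its own loads the upstream
#' artifacts from disk and fails with an explicit message when they are
#' missing.
#'
#' @param cfg a [run_config()].
#' @param stage one of the stage names or `"all"`.
#' @return invisibly, a list of the stage results computed in this call.
#' @export
run_pipeline <- function(cfg = run_config(), stage = "all") {
  stages <- c("simulate", "prep", "screen", "fit", "evaluate", "ensemble",
              "project", "classify", "centroids", "report")
  todo <- if (identical(stage, "all")) stages else match.arg(stage, stages)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  res <- list()
  for (st in todo) res[[st]] <- do.call(paste0("stage_", st), list(cfg))
  manifest <- list(config = unclass(cfg), stages_run = todo,
                   timestamp_free = TRUE)
  jsonlite::write_json(manifest, artifact(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

stage_simulate <- function(cfg) {
  spec <- cfg_spec(cfg)
  stack <- generate_stack(spec, n_layers = cfg$n_layers,
                          corr_length = cfg$corr_length,
                          seed = derive_seed(cfg$seed, "stack"))
  truth <- true_suitability(default_true_model(), stack)
  occ <- sample_occurrences(truth, cfg$n_occurrences,
                            seed = derive_seed(cfg$seed, "occurrences"),
                            contamination = if (cfg$contaminate)
                              contamination_spec() else NULL)
  write_stack(stack, artifact(cfg, "stacks", "current"),
              extra = list(seed = cfg$seed))
  for (delta in default_scenarios()) {
    sc <- apply_scenario(stack, delta)
    write_stack(sc, artifact(cfg, "stacks", delta$scenario_id))
  }
  write_raster(truth, artifact(cfg, "truth.asc"))
  write_occurrences(occ, artifact(cfg, "occurrences_raw.csv"))
  invisible(list(stack = stack, truth = truth, occurrences = occ))
}

load_current_stack <- function(cfg, stage) {
  require_artifact(artifact(cfg, "stacks", "current", "stack.json"), stage)
  read_stack(artifact(cfg, "stacks", "current"))
}

stage_prep <- function(cfg) {
  path <- require_artifact(artifact(cfg, "occurrences_raw.csv"), "prep")
  stack <- load_current_stack(cfg, "prep")
  raw <- read_occurrences(path)
  rules <- cleaning_rules(domain = c(cfg$lon_min,
                                     cfg$lon_min + cfg$n_cols * cfg$cell_size,
                                     cfg$lat_max - cfg$n_rows * cfg$cell_size,
                                     cfg$lat_max))
  cleaned <- clean_records(raw, rules)
  thinned <- thin_records(cleaned, stack$spec)
  final <- validate_on_stack(thinned, stack)
  write_occurrences(final, artifact(cfg, "occurrences_clean.csv"))
  jsonlite::write_json(attr(final, "audit"), artifact(cfg, "audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(final)
}

load_presences <- function(cfg, stage) {
  occ <- read_occurrences(require_artifact(
    artifact(cfg, "occurrences_clean.csv"), stage))
  ## statuses are re-read from the csv's status column
  tab <- utils::read.csv(artifact(cfg, "occurrences_clean.csv"),
                         stringsAsFactors = FALSE)
  occ$status <- tab$status
  occ$drop_reason <- tab$drop_reason
  occ
}

stage_screen <- function(cfg) {
  stack <- load_current_stack(cfg, "screen")
  occ <- load_presences(cfg, "screen")
  sample <- build_screening_sample(stack, occ,
                                   n_background = cfg$n_background,
                                   seed = derive_seed(cfg$seed, "screening"))
  sc <- screen_predictors(sample, r_cutoff = cfg$r_cutoff,
                          vif_threshold = cfg$vif_threshold)
  jsonlite::write_json(
    list(retained = sc$retained,
         removed_by_correlation = sc$removed_by_correlation,
         removed_by_vif = sc$removed_by_vif,
         priority = as.list(sc$priority)),
    artifact(cfg, "screening.json"), auto_unbox = FALSE, digits = NA)
  invisible(sc)
}

stage_fit <- function(cfg) {
  stack <- load_current_stack(cfg, "fit")
  occ <- load_presences(cfg, "fit")
  scr <- jsonlite::read_json(require_artifact(artifact(cfg, "screening.json"),
                                              "fit"), simplifyVector = TRUE)
  pa_sets <- draw_pseudo_absences(stack, occ, n_per_set = cfg$n_pa,
                                  n_sets = cfg$n_sets,
                                  buffer_km = cfg$buffer_km, seed = cfg$seed)
  models <- fit_replicates(make_learners(cfg$learners), stack, occ, pa_sets,
                           layers = scr$retained, frac = cfg$frac,
                           n_repeats = cfg$n_repeats, seed = cfg$seed)
  saveRDS(models, artifact(cfg, "models.rds"))
  invisible(models)
}

stage_evaluate <- function(cfg) {
  models <- readRDS(require_artifact(artifact(cfg, "models.rds"), "evaluate"))
  evals <- evaluate_replicates(models)
  utils::write.csv(evals, artifact(cfg, "replicate_scores.csv"),
                   row.names = FALSE)
  perf <- summarize_performance(evals)
  utils::write.csv(perf, artifact(cfg, "performance_table.csv"),
                   row.names = FALSE)
  invisible(evals)
}

stage_ensemble <- function(cfg) {
  models <- readRDS(require_artifact(artifact(cfg, "models.rds"), "ensemble"))
  evals <- utils::read.csv(require_artifact(
    artifact(cfg, "replicate_scores.csv"), "ensemble"),
    stringsAsFactors = FALSE)
  ens <- calibrate_ensemble(build_ensemble(models, evals, gate = cfg$tss_gate))
  saveRDS(ens, artifact(cfg, "ensemble.rds"))
  jsonlite::write_json(
    list(gate = cfg$tss_gate, cutoff = ens$cutoff,
         n_retained = length(ens$weights),
         weights = as.list(stats::setNames(ens$weights, ens$replicate_ids)),
         evaluation = as.list(ens$evaluation),
         caveat = paste("ensemble scores are apparent (computed on the",
                        "full presence + pooled pseudo-absence dataset)")),
    artifact(cfg, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  invisible(ens)
}

scenario_ids <- function() c("current", vapply(default_scenarios(),
                                               function(d) d$scenario_id,
                                               character(1)))

stage_project <- function(cfg) {
  ens <- readRDS(require_artifact(artifact(cfg, "ensemble.rds"), "project"))
  dir.create(artifact(cfg, "suitability"), showWarnings = FALSE)
  maps <- list()
  for (id in scenario_ids()) {
    stack <- read_stack(require_artifact(artifact(cfg, "stacks", id),
                                         "project"))
    maps[[id]] <- ensemble_predict(ens, stack)
    write_raster(maps[[id]], artifact(cfg, "suitability", paste0(id, ".asc")),
                 nodata = -1)
  }
  invisible(maps)
}

stage_classify <- function(cfg) {
  ens <- readRDS(require_artifact(artifact(cfg, "ensemble.rds"), "classify"))
  base_path <- artifact(cfg, "suitability", "current.asc")
  if (!file.exists(base_path))
    stop("stage 'classify' needs the projected suitability maps (",
         base_path, "); run the 'project' stage first")
  baseline <- read_raster(base_path)
  breaks <- anchored_classification(baseline, ens$cutoff,
                                    k_suitable = cfg$k_suitable)
  jsonlite::write_json(unclass(breaks), artifact(cfg, "breaks.json"),
                       auto_unbox = TRUE, digits = NA)
  areas <- cell_areas(baseline$spec)
  tabs <- list(); rows <- list()
  dir.create(artifact(cfg, "classified"), showWarnings = FALSE)
  for (id in scenario_ids()) {
    m <- read_raster(require_artifact(
      artifact(cfg, "suitability", paste0(id, ".asc")), "classify"))
    attr(m, "scenario_id") <- id
    cm <- classify_map(m, breaks)
    write_raster(cm, artifact(cfg, "classified", paste0(id, ".asc")),
                 nodata = 255)
    tabs[[id]] <- area_table(cm, areas)
    tt <- tabs[[id]]
    rec <- if (id == "current") NULL else change_stats(tabs$current, tt)
    rows[[id]] <- data.frame(
      scenario = id,
      low = area_of(tt, "low"), moderate = area_of(tt, "moderate"),
      high = area_of(tt, "high"), total = area_of(tt, "total_suitable"),
      rate_total_pct = if (is.null(rec)) NA else rec$rate_total_pct,
      rate_core_pct = if (is.null(rec)) NA else rec$rate_core_pct)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, artifact(cfg, "area_table.csv"), row.names = FALSE)
  invisible(list(breaks = breaks, tables = tabs, summary = out))
}

stage_centroids <- function(cfg) {
  require_artifact(artifact(cfg, "breaks.json"), "centroids")
  br <- jsonlite::read_json(artifact(cfg, "breaks.json"),
                            simplifyVector = TRUE)
  breaks <- class_breaks(br$cutoff, br$b1, br$b2, br$provenance)
  maps <- list()
  for (id in scenario_ids()) {
    m <- read_raster(require_artifact(
      artifact(cfg, "classified", paste0(id, ".asc")), "centroids"))
    attr(m, "breaks") <- breaks
    attr(m, "scenario_id") <- id
    class(m) <- c("classified_map", class(m))
    maps[[id]] <- m
  }
  tab <- shift_table(maps, cell_areas(maps[[1]]$spec),
                     params = cfg_albers(cfg), area_floor = cfg$area_floor)
  utils::write.csv(tab, artifact(cfg, "centroid_shifts.csv"),
                   row.names = FALSE)
  invisible(tab)
}

stage_report <- function(cfg) {
  ens <- readRDS(require_artifact(artifact(cfg, "ensemble.rds"), "report"))
  imp <- permutation_importance(ens, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, "importance"))
  utils::write.csv(imp, artifact(cfg, "importance_table.csv"),
                   row.names = FALSE)
  for (nm in ens$layers) {
    utils::write.csv(evaluation_strip(ens, nm),
                     artifact(cfg, paste0("response_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(imp)
}

#' Command-line entry point
#'
#' `Rscript -e 'ensdm::ensdm_main()' <stage> --out DIR --seed N [key=value ...]`
#' where `<stage>` is a pipeline stage or `all`.  Additional `key=value`
#' pairs override [run_config()] defaults (numeric values are coerced).
#' Exit codes: 0 ok, 1 user error, 2 internal error.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @export
ensdm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    stage <- if (length(args) && !startsWith(args[1], "--")) args[1] else "all"
    rest <- setdiff(args, stage)
    over <- list()
    i <- 1
    while (i <= length(rest)) {
      a <- rest[i]
      if (a == "--out") { over$out_dir <- rest[i + 1]; i <- i + 2 }
      else if (a == "--seed") { over$seed <- as.integer(rest[i + 1]); i <- i + 2 }
      else if (grepl("=", a, fixed = TRUE)) {
        kv <- strsplit(a, "=", fixed = TRUE)[[1]]
        val <- kv[2]
        num <- suppressWarnings(as.numeric(val))
        over[[kv[1]]] <- if (is.na(num)) val else num
        i <- i + 1
      } else stop("unrecognized argument: ", a)
    }
    cfg <- do.call(run_config, over)
    run_pipeline(cfg, stage = stage)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
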