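#' Configure the end-to-end assessment pipeline
#'
#' Bundles every stage parameter of the synthetic-world assessment pipeline:
#' simulation, monthly aggregation, stratified sampling, ensemble fitting,
#' counterfactual potential prediction, gap computation, trend fitting and
#' class summaries. Every stage that consumes randomness derives its seed
#' from the single base `seed` by a fixed offset, so one integer reproduces
#' the whole run.
#'
#' @param world Arguments for [world_config()] (list).
#' @param n_stations Stations simulated for ground validation.
#' @param probs Probability levels of the monthly aggregation.
#' @param n_total,n_min Total sample locations and per-stratum minimum.
#' @param n_rows Row count after matrix subsampling (`NULL` = keep all).
#' @param cv_folds Spatial cross-validation folds for evaluation (0 skips
#'   CV).
#' @param hyperparameters Ensemble hyperparameters
#'   ([default_hyperparameters()]).
#' @param target_year Year for potential prediction and gap (default: last
#'   simulated year).
#' @param prob_potential Probability level of potential predictions.
#' @param p_threshold Trend significance threshold.
#' @param seed Base seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(world = list(), n_stations = 12,
                            probs = c(0.05, 0.5, 0.95),
                            n_total = 400, n_min = 25, n_rows = 50000,
                            cv_folds = 5,
                            hyperparameters = default_hyperparameters(),
                            target_year = NULL, prob_potential = 0.95,
                            p_threshold = 0.005, seed = 42) {
  wc <- do.call(world_config, c(world, if (is.null(world$seed))
    list(seed = seed)))
  if (is.null(target_year)) target_year <- wc$n_years
  structure(list(
    world = wc, n_stations = n_stations, probs = probs,
    n_total = n_total, n_min = n_min, n_rows = n_rows, cv_folds = cv_folds,
    hyperparameters = hyperparameters, target_year = target_year,
    prob_potential = prob_potential, p_threshold = p_threshold,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "aggregate", "sample", "fit", "potential",
                     "gap", "trend", "summarize", "validate_stations")

# write a stage manifest: parameters, seed, output files with checksums
write_manifest <- function(stage, out_dir, params, seed, outputs) {
  manifest <- list(
    stage = stage, seed = seed, params = params,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Executes a single named stage against the accumulated pipeline state,
#' writes the stage outputs and a JSON manifest (parameters, seed, output
#' checksums) into `out_dir`, and returns the updated state. Reruns with
#' identical inputs produce identical manifests. Stages must run in
#' [PIPELINE_STAGES] order; missing prerequisites raise an error naming the
#' missing piece.
#'
#' @param stage Stage name, one of `PIPELINE_STAGES`.
#' @param state Named list of accumulated results (empty list to start).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The updated state, with `state$manifests` extended.
#' @export
run_pipeline_stage <- function(stage, state, config, out_dir) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(what) {
    if (is.null(state[[what]]))
      stop(sprintf("stage '%s' requires missing input '%s'", stage, what),
           call. = FALSE)
    state[[what]]
  }
  outputs <- character(0)
  params <- list()
  seed <- config$seed

  if (stage == "simulate") {
    state$world <- generate_world(config$world)
    state$stations <- generate_stations(state$world, config$n_stations,
                                        seed = config$seed + 1L)
    p <- file.path(out_dir, "stations.csv")
    write_stations_csv(state$stations$measurements, p)
    outputs <- p
    params <- unclass(config$world)
  } else if (stage == "aggregate") {
    world <- need("world")
    state$monthly <- aggregate_monthly(world, probs = config$probs)
    params <- list(probs = config$probs)
  } else if (stage == "sample") {
    world <- need("world")
    monthly <- need("monthly")
    nl_change <- world$pressure_end$nightlights -
      world$pressure_start$nightlights
    state$strata <- classify_strata(nl_change, world$lc_first,
                                    world$lc_last, world$pressure_start,
                                    world$pressure_end)
    quarters <- c(1, 4, 7, 10)
    imgs <- c(lapply(quarters, function(m)
                monthly_layer(monthly, 1, m, 0.5)),
              lapply(quarters, function(m)
                monthly_layer(monthly, world$config$n_years, m, 0.5)))
    stats <- stratum_stats(state$strata, imgs)
    state$design <- stratum_table(stats, config$n_total, config$n_min)
    state$points <- draw_points(state$strata, state$design, world$grid,
                                seed = config$seed + 2L)
    covs <- world_covariates(world)
    state$covariates <- covs
    m <- build_regression_matrix(state$points, monthly, covs)
    if (!is.null(config$n_rows) && config$n_rows < nrow(m))
      m <- subsample_matrix(m, config$n_rows, seed = config$seed + 3L)
    state$matrix <- m
    p1 <- file.path(out_dir, "points.csv")
    utils::write.csv(state$points, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "stratum_table.csv")
    utils::write.csv(as.data.frame(state$design), p2, row.names = FALSE)
    p3 <- file.path(out_dir, "registry.json")
    write_registry(covs, p3)
    outputs <- c(p1, p2, p3)
    params <- list(n_total = config$n_total, n_min = config$n_min,
                   n_rows = config$n_rows)
    seed <- config$seed + 2L
  } else if (stage == "fit") {
    m <- need("matrix")
    if (config$cv_folds >= 2) {
      state$cv <- cross_validate(m, k = config$cv_folds,
                                 hyperparameters = config$hyperparameters,
                                 seed = config$seed + 4L)
      p <- file.path(out_dir, "cv_report.json")
      jsonlite::write_json(unclass(state$cv$pooled), p, auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, p)
    }
    state$model <- fapar_eml(m, hyperparameters = config$hyperparameters,
                             seed = config$seed + 5L)
    params <- list(cv_folds = config$cv_folds)
    seed <- config$seed + 5L
  } else if (stage == "potential") {
    world <- need("world")
    model <- need("model")
    covs <- need("covariates")
    scenario <- build_potential_scenario(covs, world$biome)
    state$potential <- predict_potential(model, scenario,
                                         year = config$target_year,
                                         prob = config$prob_potential)
    params <- list(target_year = config$target_year,
                   prob = config$prob_potential)
  } else if (stage == "gap") {
    monthly <- need("monthly")
    pot <- need("potential")
    actual <- monthly_year_stack(monthly, config$target_year,
                                 config$prob_potential)
    state$gap <- compute_gap(actual, pot$potential)
    p <- file.path(out_dir, "gap_annual.tsv")
    write_raster(state$gap$annual, p, monthly$grid)
    outputs <- p
    params <- list(target_year = config$target_year)
  } else if (stage == "trend") {
    monthly <- need("monthly")
    state$trend <- trend_raster(monthly, prob = config$prob_potential)
    for (nm in c("beta", "p")) {
      pth <- file.path(out_dir, sprintf("trend_%s.tsv", nm))
      write_raster(state$trend[[nm]], pth, monthly$grid)
      outputs <- c(outputs, pth)
    }
    params <- list(prob = config$prob_potential)
  } else if (stage == "summarize") {
    world <- need("world")
    gap <- need("gap")
    trend <- need("trend")
    classes <- lc_change_classes(world$lc_first, world$lc_last)
    state$summary <- summarize_by_class(gap$annual, trend, classes,
                                        p_threshold = config$p_threshold)
    p <- file.path(out_dir, "class_summary.csv")
    utils::write.csv(state$summary, p, row.names = FALSE)
    outputs <- p
    params <- list(p_threshold = config$p_threshold)
  } else if (stage == "validate_stations") {
    monthly <- need("monthly")
    st <- need("stations")
    means <- station_monthly_means(st$measurements)
    state$station_match <- match_stations(monthly, st$stations, means,
                                          prob = 0.5)
    p <- file.path(out_dir, "station_match.csv")
    utils::write.csv(state$station_match, p, row.names = FALSE)
    outputs <- p
  }

  state$manifests <- c(state$manifests,
                       stats::setNames(
                         list(write_manifest(stage, out_dir, params, seed,
                                             outputs)), stage))
  state
}

#' Run the full assessment pipeline
#'
#' Runs all (or a prefix of) pipeline stages in order on a fresh state and
#' returns the final state: the simulated world, monthly series, sampling
#' design, fitted ensemble with its cross-validation report, potential and
#' gap rasters, trend rasters and the class summary.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage artifacts and manifests.
#' @param stages Stages to run (default all, in order).
#' @return The final pipeline state (named list).
#' @export
run_fapar_pipeline <- function(config, out_dir = tempfile("fapargap_"),
                               stages = PIPELINE_STAGES) {
  state <- list()
  for (s in stages)
    state <- run_pipeline_stage(s, state, config, out_dir)
  state$out_dir <- out_dir
  state
}
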