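# End-to-end orchestration: synthesize -> filter -> scale-optimize ->
# select -> fit -> evaluate -> validate -> gap analysis.

#' Full pipeline configuration
#'
#' Bundles every tunable of the pipeline with the defaults used throughout:
#' 30-day minimum effort, 500 m dedupe buffer, the 7-scale ladder, |r| > 0.7
#' correlation pruning, VIF > 5 collinearity removal, 10 balanced bootstrap
#' replicates, a 4:1 train/test partition, 30 classification thresholds and
#' Boyce windows of 0.1 of the range at 101 midpoints. The synthetic
#' landscape block describes the study conditions the generator emulates:
#' a 256 x 256 grid at 250 m, clustered multi-survey deployments of ~1500
#' stations and a rare species (target prevalence 0.095).
#'
#' @param landscape a [landscape_config()].
#' @param truth a [true_model()].
#' @param surveys a [survey_config()].
#' @param n_validation number of independent validation points.
#' @param min_effort_days,dedupe_radius,scales,cor_threshold,vif_threshold,n_replicates,n_thresholds,train_frac,balance_below,boyce_window,boyce_n_windows pipeline constants (see Details / function docs of each stage).
#' @param truncate_radius optional kernel truncation override (meters).
#' @param seed master seed; stage seeds are spawned from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(n_predictors = 4,
                                                    correlation_lengths = c(1500, 3000, 6000, 2500),
                                                    seed = 1L),
                       truth = true_model(c("env1", "env2", "env3"),
                                          true_scales = c(500, 2000, 8000),
                                          coefficients = c(1, -0.8, 0.7),
                                          intercept = -3),
                       surveys = survey_config(),
                       n_validation = 149,
                       min_effort_days = 30, dedupe_radius = 500,
                       scales = default_scales(),
                       cor_threshold = 0.7, vif_threshold = 5,
                       n_replicates = 10, n_thresholds = 30,
                       train_frac = 0.8, balance_below = 0.1,
                       boyce_window = 0.1, boyce_n_windows = 101,
                       truncate_radius = NULL,
                       seed = 1L) {
  stopifnot(min_effort_days > 0, dedupe_radius > 0, all(diff(scales) > 0),
            cor_threshold > 0, vif_threshold > 0, n_replicates >= 1,
            n_thresholds >= 1, train_frac > 0, train_frac < 1)
  structure(list(landscape = landscape, truth = truth, surveys = surveys,
                 n_validation = as.integer(n_validation),
                 min_effort_days = min_effort_days, dedupe_radius = dedupe_radius,
                 scales = as.numeric(scales), cor_threshold = cor_threshold,
                 vif_threshold = vif_threshold, n_replicates = as.integer(n_replicates),
                 n_thresholds = as.integer(n_thresholds), train_frac = train_frac,
                 balance_below = balance_below, boyce_window = boyce_window,
                 boyce_n_windows = as.integer(boyce_n_windows),
                 truncate_radius = truncate_radius, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat-key YAML file whose blocks mirror the [run_config()]
#' arguments (`landscape:`, `truth:`, `surveys:` plus top-level constants).
#' Keys left out fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$landscape)) args$landscape <- do.call(landscape_config, y$landscape)
  if (!is.null(y$truth)) args$truth <- do.call(true_model, y$truth)
  if (!is.null(y$surveys)) {
    sv <- y$surveys
    if (!is.null(sv$effort_days_range)) sv$effort_days_range <- unlist(sv$effort_days_range)
    if (!is.null(sv$year_range)) sv$year_range <- unlist(sv$year_range)
    args$surveys <- do.call(survey_config, sv)
  }
  scalars <- intersect(names(y), setdiff(names(formals(run_config)),
                                         c("landscape", "truth", "surveys")))
  for (k in scalars) args[[k]] <- if (k == "scales") unlist(y[[k]]) else y[[k]]
  do.call(run_config, args)
}

run_one_replicate <- function(dataset, values, stations_by_id, config, part_seed) {
  dataset <- partition_train_test(dataset, config$train_frac, part_seed)
  rows <- dataset$rows
  vr <- values[match(rows$station_id, values$station_id), , drop = FALSE]
  cc <- stats::complete.cases(vr)
  rows <- rows[cc, , drop = FALSE]; vr <- vr[cc, , drop = FALSE]
  tr <- rows$split == "train"
  scan <- univariate_scale_scan(vr[tr, , drop = FALSE], rows$detected[tr],
                                scales = config$scales)
  cand <- prune_correlated(scan, vr[tr, , drop = FALSE], config$cor_threshold)
  cand <- vif_filter(cand, vr[tr, , drop = FALSE], config$vif_threshold)
  ranking <- all_subsets(cand, vr[tr, , drop = FALSE], rows$detected[tr])
  best <- top_model(ranking)
  # evaluate on the held-out rows with the training-standardized model
  te <- rows$split == "test"
  co <- best$coefficients
  eta <- rep(co$estimate[co$term == "(Intercept)"], sum(te))
  for (tm in co$term[co$term != "(Intercept)"]) {
    z <- (vr[[tm]][te] - best$scaling$mean[[tm]]) / best$scaling$sd[[tm]]
    eta <- eta + co$estimate[co$term == tm] * z
  }
  metrics <- sweep_thresholds(stats::plogis(eta), rows$detected[te],
                              config$n_thresholds)
  optimum <- select_optimal_threshold(metrics)
  list(dataset = dataset, scan = scan, candidates = cand, ranking = ranking,
       model = best, metrics = metrics, optimum = optimum)
}

#' Run the full multi-scale habitat-suitability analysis
#'
#' Executes every stage on a synthetic landscape with a known ground truth:
#' generates predictors, the true suitability surface, clustered camera
#' surveys, validation points and zones; filters stations (minimum effort,
#' 500 m dedupe, undetecting-survey removal); builds the scale-smoothed
#' stack and extracts station values; then, per bootstrap-balanced
#' replicate, re-runs scale optimization, correlation/VIF screening,
#' all-subsets AICc ranking and the threshold sweep on the held-out split.
#' The best replicate's top model produces the suitability map, which is
#' validated with the continuous Boyce index against the independent points
#' and discretized for the protected-area gap analysis.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all tables (CSV), rasters
#'   (`.asc`), zones (GeoJSON) and a machine-readable run manifest (JSON)
#'   are written there.
#' @return (invisibly) a list with every intermediate and final artifact;
#'   see the manifest for the file layout.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- spawn_seeds(config$seed, 4 + config$n_replicates)
  config$landscape$seed <- seeds[1]
  config$surveys$seed <- seeds[2]

  predictors <- generate_predictor_stack(config$landscape)
  truth_raster <- compute_true_suitability(predictors, config$truth, config$scales,
                                           config$truncate_radius)
  stations <- simulate_surveys(truth_raster, config$surveys)
  validation <- simulate_validation_points(truth_raster, config$n_validation,
                                           seed = seeds[3])
  zones <- simulate_zones(truth_raster, seed = seeds[4])

  filtered <- filter_min_effort(stations, config$min_effort_days)
  filtered <- dedupe_within_buffer(filtered, config$dedupe_radius)
  filtered <- drop_undetecting_surveys(filtered)
  prev <- prevalence(filtered)
  message(sprintf("prevalence after filtering: %.4f (%d presences / %d stations)",
                  prev, sum(filtered$detected), nrow(filtered)))
  if (prev >= config$balance_below)
    message("prevalence above the balancing gate; balanced replicates still built for comparability")

  stack <- build_scaled_stack(predictors, config$scales, config$truncate_radius)
  values <- extract_at_stations(stack, filtered)

  datasets <- bootstrap_balanced(filtered, config$n_replicates, seed = config$seed)
  replicates <- lapply(seq_along(datasets), function(i)
    run_one_replicate(datasets[[i]], values, filtered, config, seeds[4 + i]))

  optima <- do.call(rbind, lapply(seq_along(replicates), function(i)
    cbind(replicate_id = i, replicates[[i]]$optimum)))
  best_row <- select_best_replicate(optima)
  best <- replicates[[best_row$replicate_id]]

  suitability <- predict_suitability(best$model, stack)
  cellv <- point_to_cell(suitability, validation$x, validation$y)
  val_suit <- suitability$values[cbind(cellv$row, cellv$col)]
  boyce <- continuous_boyce(val_suit,
                            suitability$values[is.finite(suitability$values)],
                            config$boyce_window, config$boyce_n_windows)
  classes <- bin_suitability(suitability)
  gap <- zonal_area(classes, zones)
  protection <- protection_summary(classes, zones)

  result <- list(config = config, predictors = predictors, truth_raster = truth_raster,
                 stations = stations, filtered = filtered, prevalence = prev,
                 validation = validation, zones = zones, stack = stack,
                 values = values, replicates = replicates, optima = optima,
                 best_replicate = best_row$replicate_id, model = best$model,
                 suitability = suitability, boyce = boyce, classes = classes,
                 gap = gap, protection = protection)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir, seeds)
  invisible(result)
}

write_run_artifacts <- function(result, out_dir, seeds) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(result$stations, p("stations_raw.csv"), row.names = FALSE)
  utils::write.csv(result$filtered, p("stations_filtered.csv"), row.names = FALSE)
  utils::write.csv(result$validation, p("validation_points.csv"), row.names = FALSE)
  write_zones_geojson(result$zones, p("zones.geojson"))
  best <- result$replicates[[result$best_replicate]]
  utils::write.csv(best$scan$table, p("scale_selection.csv"), row.names = FALSE)
  utils::write.csv(best$candidates$removed, p("predictor_removals.csv"), row.names = FALSE)
  utils::write.csv(best$ranking$table, p("model_ranking.csv"), row.names = FALSE)
  utils::write.csv(coefficient_table(result$model), p("coefficients.csv"), row.names = FALSE)
  utils::write.csv(result$optima, p("replicate_optima.csv"), row.names = FALSE)
  utils::write.csv(best$metrics, p("threshold_metrics.csv"), row.names = FALSE)
  utils::write.csv(result$boyce$windows, p("boyce_windows.csv"), row.names = FALSE)
  utils::write.csv(result$gap, p("gap_table.csv"), row.names = FALSE)
  utils::write.csv(result$protection, p("protection_summary.csv"), row.names = FALSE)
  write_asc(result$suitability, p("suitability.asc"))
  write_asc(result$classes, p("suitability_class.asc"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("scalesuit")),
    master_seed = result$config$seed,
    stage_seeds = as.integer(seeds),
    prevalence = result$prevalence,
    best_replicate = result$best_replicate,
    optimal_threshold = best$optimum$threshold,
    binary_auc = best$optimum$binary_auc,
    tss = best$optimum$tss,
    kappa = best$optimum$kappa,
    boyce_index = result$boyce$index,
    n_stations_filtered = nrow(result$filtered),
    config = list(
      min_effort_days = result$config$min_effort_days,
      dedupe_radius = result$config$dedupe_radius,
      scales = result$config$scales,
      cor_threshold = result$config$cor_threshold,
      vif_threshold = result$config$vif_threshold,
      n_replicates = result$config$n_replicates,
      n_thresholds = result$config$n_thresholds,
      train_frac = result$config$train_frac,
      target_prevalence = result$config$surveys$target_prevalence))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
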