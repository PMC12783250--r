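#' Configuration of a synthetic landscape
#'
#' Describes the raster grid and the spatial autocorrelation of each
#' synthetic environmental predictor. Predictors are stationary Gaussian
#' random fields with approximately zero mean, unit variance and an
#' e-folding correlation length set per predictor.
#'
#' @param grid_rows,grid_cols grid dimensions (positive integers).
#' @param pixel_size cell size in meters.
#' @param n_predictors number of predictor fields.
#' @param correlation_lengths numeric vector of correlation lengths in meters,
#'   one per predictor (recycled if length 1).
#' @param seed integer RNG seed; fields are pure functions of (config, index).
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(grid_rows = 256, grid_cols = 256, pixel_size = 250,
                             n_predictors = 4,
                             correlation_lengths = rep(2000, n_predictors),
                             seed = 1L) {
  if (length(correlation_lengths) == 1L)
    correlation_lengths <- rep(correlation_lengths, n_predictors)
  stopifnot(grid_rows >= 1, grid_cols >= 1, pixel_size > 0,
            n_predictors >= 1, length(correlation_lengths) == n_predictors,
            all(correlation_lengths > 0))
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 pixel_size = as.numeric(pixel_size),
                 n_predictors = as.integer(n_predictors),
                 correlation_lengths = as.numeric(correlation_lengths),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Ground-truth species-habitat model
#'
#' The generative analogue of the fitted logistic model: suitability is
#' `plogis(intercept + sum(coef_j * z_j))` where `z_j` is the predictor
#' smoothed at its true scale and standardized over the landscape.
#'
#' @param active_predictors names of the predictors with non-zero effects.
#' @param true_scales smoothing scale (meters) per active predictor; must be
#'   drawn from the analysis scale ladder in use.
#' @param coefficients effect size per active predictor (on the standardized
#'   smoothed predictor).
#' @param intercept intercept on the logit scale; controls baseline
#'   prevalence (e.g. -3 gives a rare species).
#' @return object of class `true_model`.
#' @export
true_model <- function(active_predictors, true_scales, coefficients, intercept = -3) {
  stopifnot(length(active_predictors) == length(coefficients),
            length(active_predictors) == length(true_scales))
  structure(list(active_predictors = as.character(active_predictors),
                 true_scales = as.numeric(true_scales),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept)),
            class = "true_model")
}

#' Configuration of simulated camera-trap surveys
#'
#' Surveys are spatial clusters of camera stations, mimicking independent
#' research groups each deploying a grid in one part of the landscape.
#'
#' @param n_surveys number of survey clusters.
#' @param stations_per_survey stations per cluster.
#' @param survey_extent cluster radius in meters.
#' @param effort_days_range integer pair: min/max operational days per
#'   station (uniform).
#' @param target_prevalence desired overall fraction of deployed stations
#'   with a detection, in (0, 1); a detection scaler is calibrated to reach
#'   it. The default 0.075 is set so that after effort filtering and
#'   presence-preserving 500 m thinning the analysis table lands near the
#'   low-prevalence regime (~0.09, < 0.1) typical of rare-species
#'   camera-trap data.
#' @param year_range integer pair of survey years (each survey draws one).
#' @param seed integer RNG seed.
#' @return object of class `survey_config`.
#' @export
survey_config <- function(n_surveys = 7, stations_per_survey = 222,
                          survey_extent = 15000, effort_days_range = c(10, 120),
                          target_prevalence = 0.075, year_range = c(2008, 2021),
                          seed = 1L) {
  stopifnot(n_surveys >= 1, stations_per_survey >= 1, survey_extent > 0,
            length(effort_days_range) == 2, effort_days_range[1] >= 1,
            effort_days_range[1] <= effort_days_range[2],
            target_prevalence > 0, target_prevalence < 1)
  structure(list(n_surveys = as.integer(n_surveys),
                 stations_per_survey = as.integer(stations_per_survey),
                 survey_extent = as.numeric(survey_extent),
                 effort_days_range = as.integer(effort_days_range),
                 target_prevalence = as.numeric(target_prevalence),
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "survey_config")
}

#' Generate one spatially autocorrelated predictor field
#'
#' Draws a stationary Gaussian random field by circular convolution of white
#' noise with a Gaussian kernel (spectral synthesis on the torus), then
#' standardizes to zero mean and unit variance. The kernel standard deviation
#' is half the configured correlation length, giving an autocorrelation
#' function close to `exp(-(h/L)^2)` (e-folding at lag `L`). Deterministic
#' given `(config, predictor_index)`.
#'
#' @param config a [landscape_config()].
#' @param predictor_index which predictor (1-based, `<= n_predictors`).
#' @return a [predictor_raster()] named `"env<index>"`.
#' @export
generate_random_field <- function(config, predictor_index) {
  stopifnot(inherits(config, "landscape_config"),
            predictor_index >= 1, predictor_index <= config$n_predictors)
  nr <- config$grid_rows; nc <- config$grid_cols
  L_px <- config$correlation_lengths[predictor_index] / config$pixel_size
  field <- with_seed(config$seed + 7919L * as.integer(predictor_index), {
    white <- matrix(stats::rnorm(nr * nc), nr, nc)
    sigma <- L_px / 2
    if (sigma < 0.3) {
      white  # below grid resolution: white noise already has the target ACF
    } else {
      # periodic Gaussian kernel centered at (1,1) so circular convolution
      # via FFT is exactly stationary on the torus
      di <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
      dj <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
      k <- exp(-outer(di^2, dj^2, "+") / (2 * sigma^2))
      Re(stats::fft(stats::fft(white) * stats::fft(k / sum(k)), inverse = TRUE)) / (nr * nc)
    }
  })
  field <- (field - mean(field)) / stats::sd(field)
  predictor_raster(field, config$pixel_size,
                   origin = c(0, nr * config$pixel_size),
                   name = sprintf("env%d", predictor_index))
}

#' Generate the full synthetic predictor set
#'
#' @param config a [landscape_config()].
#' @return list of [predictor_raster()] objects `env1..envP`.
#' @export
generate_predictor_stack <- function(config) {
  lapply(seq_len(config$n_predictors), function(i) generate_random_field(config, i))
}

#' True suitability surface under a known species-habitat model
#'
#' Smooths each active predictor at its true scale, standardizes the smoothed
#' layer over the landscape (valid cells), and applies the inverse-logit
#' linear predictor of the [true_model()]. Values lie in `[0, 1]`.
#'
#' @param predictors list of [predictor_raster()] (the raw fields).
#' @param model a [true_model()].
#' @param scales the supported scale ladder; every true scale must belong to
#'   it.
#' @param truncate_radius kernel truncation passed to [focal_smooth()].
#' @return probability raster (`predictor_raster` named `"truth"`).
#' @export
compute_true_suitability <- function(predictors, model, scales = default_scales(),
                                     truncate_radius = NULL) {
  stopifnot(inherits(model, "true_model"))
  nms <- vapply(predictors, `[[`, "", "name")
  missing <- setdiff(model$active_predictors, nms)
  if (length(missing))
    stop("active predictor(s) not in the stack: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(model$true_scales, scales)
  if (length(bad))
    stop("true scale(s) outside the supported scale set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ref <- predictors[[1L]]
  eta <- matrix(model$intercept, nrow(ref$values), ncol(ref$values))
  for (i in seq_along(model$active_predictors)) {
    p <- predictors[[match(model$active_predictors[i], nms)]]
    sm <- focal_smooth(p, model$true_scales[i],
                       truncate_radius %||% model$true_scales[i])$values
    z <- (sm - mean(sm, na.rm = TRUE)) / stats::sd(sm, na.rm = TRUE)
    eta <- eta + model$coefficients[i] * z
  }
  predictor_raster(stats::plogis(eta), ref$pixel_size, ref$origin, name = "truth")
}

# Bisection calibration of the detection scaler q so that
# mean(pmin(1, q * p)) over station pixels hits the target prevalence.
calibrate_detection_scaler <- function(p, target) {
  f <- function(q) mean(pmin(1, q * p)) - target
  if (f(0) >= 0) return(0)
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) {
    warning("target prevalence unreachable even with saturated detection; using scaler ",
            hi, call. = FALSE)
    return(hi)
  }
  lo <- 0
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate clustered camera-trap surveys with rare detections
#'
#' Places `n_surveys` cluster centers uniformly over the landscape (inset by
#' the cluster radius), scatters stations uniformly within each cluster disc,
#' assigns uniform operational effort and a survey year, and draws detections
#' `Bernoulli(min(1, q * truth))` where the detection scaler `q` is
#' calibrated by bisection so the expected prevalence matches
#' `target_prevalence`. Deterministic given the config seed.
#'
#' @param truth probability raster from [compute_true_suitability()].
#' @param cfg a [survey_config()].
#' @return a station table (see [station_table()]) with attribute
#'   `"detection_scaler"`.
#' @export
simulate_surveys <- function(truth, cfg) {
  stopifnot(inherits(truth, "predictor_raster"), inherits(cfg, "survey_config"))
  ext <- raster_extent(truth)
  R <- cfg$survey_extent
  if (ext["xmax"] - ext["xmin"] <= 2 * R || ext["ymax"] - ext["ymin"] <= 2 * R)
    stop("survey cluster radius exceeds the raster extent: clusters would fall outside",
         call. = FALSE)
  with_seed(cfg$seed, {
    cx <- stats::runif(cfg$n_surveys, ext["xmin"] + R, ext["xmax"] - R)
    cy <- stats::runif(cfg$n_surveys, ext["ymin"] + R, ext["ymax"] - R)
    years <- sample(seq(cfg$year_range[1], cfg$year_range[2]),
                    cfg$n_surveys, replace = TRUE)
    rows <- vector("list", cfg$n_surveys)
    for (s in seq_len(cfg$n_surveys)) {
      n <- cfg$stations_per_survey
      # uniform in the disc
      th <- stats::runif(n, 0, 2 * pi)
      rr <- R * sqrt(stats::runif(n))
      rows[[s]] <- data.frame(
        station_id = sprintf("SV%02d-%04d", s, seq_len(n)),
        survey_id = sprintf("SV%02d", s),
        x = cx[s] + rr * cos(th), y = cy[s] + rr * sin(th),
        year = years[s],
        effort_days = sample(seq(cfg$effort_days_range[1], cfg$effort_days_range[2]),
                             n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    st <- do.call(rbind, rows)
    cell <- point_to_cell(truth, st$x, st$y)
    p <- truth$values[cbind(cell$row, cell$col)]
    p[is.na(p)] <- 0
    q <- calibrate_detection_scaler(p, cfg$target_prevalence)
    st$detected <- stats::rbinom(nrow(st), 1L, pmin(1, q * p))
    attr(st, "detection_scaler") <- q
    station_table(st)
  })
}

#' Simulate opportunistic presence-only validation points
#'
#' Samples point locations with probability proportional to suitability via
#' rejection sampling over valid cells (uniform jitter within the accepted
#' pixel), emulating opportunistic encounter records used for independent
#' validation.
#'
#' @param truth probability raster.
#' @param n_points number of points (default 149, a typical size for a
#'   multi-year opportunistic rescue record set).
#' @param seed integer RNG seed.
#' @return data frame with `point_id`, `x`, `y`.
#' @export
simulate_validation_points <- function(truth, n_points = 149, seed = 1L) {
  stopifnot(inherits(truth, "predictor_raster"), n_points >= 1)
  v <- truth$values
  ok <- which(is.finite(v) & v > 0)
  if (length(ok) == 0)
    stop("truth raster has no positive suitability: no valid sampling density",
         call. = FALSE)
  pmax_ <- max(v[ok])
  px <- truth$pixel_size
  with_seed(seed, {
    xs <- numeric(n_points); ys <- numeric(n_points)
    got <- 0L
    while (got < n_points) {
      take <- (n_points - got) * 3L + 32L
      cand <- ok[sample.int(length(ok), take, replace = TRUE)]
      acc <- cand[stats::runif(take) < v[cand] / pmax_]
      if (length(acc) == 0) next
      acc <- acc[seq_len(min(length(acc), n_points - got))]
      r <- (acc - 1L) %% nrow(v) + 1L
      c_ <- (acc - 1L) %/% nrow(v) + 1L
      idx <- got + seq_along(acc)
      xs[idx] <- truth$origin[1] + (c_ - 1L + stats::runif(length(acc))) * px
      ys[idx] <- truth$origin[2] - (r - 1L + stats::runif(length(acc))) * px
      got <- got + length(acc)
    }
    data.frame(point_id = sprintf("V%04d", seq_len(n_points)), x = xs, y = ys,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic protected-area and community land-use zones
#'
#' Lays rectangular zone polygons over the landscape: `n_protected` protected
#' blocks plus one rectangle per community land-use class (paddy, oil-palm
#' smallholding, community mosaic). Rectangles are placed uniformly at random
#' with side lengths drawn as a fraction of the extent; purely synthetic
#' geometry for exercising the gap-analysis stage.
#'
#' @param r a raster defining the extent.
#' @param n_protected number of protected rectangles.
#' @param land_use_classes character vector of land-use zone names.
#' @param seed integer RNG seed.
#' @return a [zone_set()].
#' @export
simulate_zones <- function(r, n_protected = 3,
                           land_use_classes = c("paddy", "oil-palm smallholding",
                                                "community mosaic"),
                           seed = 1L) {
  ext <- raster_extent(r)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  rect <- function(x0, y0, w, h) {
    cbind(x = c(x0, x0 + w, x0 + w, x0, x0), y = c(y0, y0, y0 + h, y0 + h, y0))
  }
  with_seed(seed, {
    zones <- list()
    for (i in seq_len(n_protected)) {
      w <- stats::runif(1, 0.15, 0.3) * W; h <- stats::runif(1, 0.15, 0.3) * H
      zones[[length(zones) + 1L]] <- list(
        name = sprintf("PA-%d", i), protected = TRUE, land_use = NA_character_,
        rings = list(rect(stats::runif(1, ext["xmin"], ext["xmax"] - w),
                          stats::runif(1, ext["ymin"], ext["ymax"] - h), w, h)))
    }
    for (lu in land_use_classes) {
      w <- stats::runif(1, 0.1, 0.25) * W; h <- stats::runif(1, 0.1, 0.25) * H
      zones[[length(zones) + 1L]] <- list(
        name = lu, protected = FALSE, land_use = lu,
        rings = list(rect(stats::runif(1, ext["xmin"], ext["xmax"] - w),
                          stats::runif(1, ext["ymin"], ext["ymax"] - h), w, h)))
    }
    zone_set(zones)
  })
}
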