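#' The default analysis scale ladder
#'
#' Seven spatial scales (meters) spanning the plausible range of home-range
#' sizes for a medium-sized forest mammal: 0.25, 0.5, 1, 2, 4, 8 and 16 km.
#' Each scale is the radius of the Gaussian smoothing neighbourhood used to
#' compute focal means.
#'
#' @return strictly increasing numeric vector of scales in meters.
#' @export
default_scales <- function() c(250, 500, 1000, 2000, 4000, 8000, 16000)

#' Truncated Gaussian focal-mean kernel
#'
#' Builds the normalized weight matrix for a Gaussian neighbourhood of radius
#' `scale` meters with standard deviation `scale / 2`, truncated (set to zero)
#' beyond `truncate_radius` from the center. The matrix has side
#' `2 * ceiling(scale / pixel_size) + 1` and its weights sum to one.
#'
#' @param scale neighbourhood radius in meters; must be at least `pixel_size`.
#' @param pixel_size raster cell size in meters.
#' @param truncate_radius hard truncation radius in meters (default: `scale`,
#'   i.e. two standard deviations).
#' @return square numeric matrix of weights summing to 1.
#' @export
gaussian_kernel <- function(scale, pixel_size, truncate_radius = scale) {
  if (scale < pixel_size)
    stop(sprintf("scale (%g m) must be >= pixel_size (%g m): kernel degenerates to a point",
                 scale, pixel_size), call. = FALSE)
  r <- ceiling(scale / pixel_size)
  idx <- (-r):r
  d2 <- outer(idx^2, idx^2, "+") * pixel_size^2
  sigma <- scale / 2
  w <- exp(-d2 / (2 * sigma^2))
  w[sqrt(d2) > truncate_radius] <- 0
  w / sum(w)
}

# Linear ("same") 2-D convolution via zero-padded FFT. `k` must have odd
# dimensions so the output aligns with the input grid.
conv2d_same <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x); kr <- nrow(k); kc <- ncol(k)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  X <- matrix(0, pr, pc); X[seq_len(nr), seq_len(nc)] <- x
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc)]
}

#' Gaussian focal smoothing of a raster
#'
#' Replaces each valid cell with the kernel-weighted mean of the valid cells
#' in its neighbourhood ([gaussian_kernel()]). Near raster edges and nodata
#' cells the weights are renormalized over the available cells, so no values
#' are invented outside the extent; nodata cells stay nodata. Geometry
#' (origin, pixel size, dimensions) is preserved.
#'
#' @param r a [predictor_raster()].
#' @param scale smoothing scale (neighbourhood radius) in meters.
#' @param truncate_radius kernel truncation radius in meters, default `scale`.
#' @return a `predictor_raster` of identical geometry, named
#'   `"<name>_<scale>m"`.
#' @export
focal_smooth <- function(r, scale, truncate_radius = scale) {
  stopifnot(inherits(r, "predictor_raster"))
  valid <- is.finite(r$values)
  if (!any(valid)) stop("raster is entirely nodata; nothing to smooth", call. = FALSE)
  k <- gaussian_kernel(scale, r$pixel_size, truncate_radius)
  v0 <- r$values
  v0[!valid] <- 0
  num <- conv2d_same(v0, k)
  den <- conv2d_same(valid + 0, k)
  out <- num / den
  out[!valid] <- NA_real_
  predictor_raster(out, r$pixel_size, r$origin,
                   name = sprintf("%s_%gm", r$name, scale), year = r$year)
}

#' Smooth a predictor set over the scale ladder
#'
#' Applies [focal_smooth()] to every input layer at every scale, producing
#' the stack of scale-specific focal-mean rasters that downstream scale
#' selection and prediction operate on. Layers sharing a `name` but differing
#' in `year` are kept as parallel year-specific entries.
#'
#' @param predictors list of [predictor_raster()] objects (co-registered:
#'   identical geometry).
#' @param scales numeric vector of scales in meters, default
#'   [default_scales()].
#' @param truncate_radius kernel truncation radius; default equals each scale.
#' @return an object of class `scaled_stack`.
#' @export
build_scaled_stack <- function(predictors, scales = default_scales(),
                               truncate_radius = NULL) {
  stopifnot(length(predictors) > 0, all(diff(scales) > 0))
  entries <- list()
  for (p in predictors) {
    stopifnot(inherits(p, "predictor_raster"))
    for (s in scales) {
      entries[[length(entries) + 1L]] <- list(
        name = p$name, year = p$year, scale = s,
        raster = focal_smooth(p, s, truncate_radius %||% s))
    }
  }
  structure(list(entries = entries, scales = as.numeric(scales),
                 names = unique(vapply(predictors, `[[`, "", "name"))),
            class = "scaled_stack")
}

#' @export
print.scaled_stack <- function(x, ...) {
  cat(sprintf("<scaled_stack> %d predictors x %d scales (%s m), %d layers\n",
              length(x$names), length(x$scales),
              paste(x$scales, collapse = ", "), length(x$entries)))
  invisible(x)
}

# All stack entries for one (predictor, scale); >1 entry means year layers.
stack_layers <- function(stack, name, scale) {
  hit <- vapply(stack$entries, function(e) e$name == name && e$scale == scale, TRUE)
  if (!any(hit))
    stop(sprintf("no layer '%s' at scale %g m in the stack", name, scale), call. = FALSE)
  stack$entries[hit]
}

# Single layer for (predictor, scale), year-matched: nearest year wins, ties
# broken toward the earlier year; NA target year takes the first layer.
stack_get <- function(stack, name, scale, year = NA) {
  layers <- stack_layers(stack, name, scale)
  if (length(layers) == 1L || is.na(year)) return(layers[[1L]]$raster)
  yrs <- vapply(layers, `[[`, 1L, "year")
  if (all(is.na(yrs))) return(layers[[1L]]$raster)
  d <- abs(yrs - year)
  d[is.na(d)] <- Inf
  best <- which(d == min(d))
  layers[[best[which.min(yrs[best])]]]$raster
}

#' Extract scale-smoothed predictor values at camera stations
#'
#' Looks up, for every station, the value of each (predictor, scale) layer at
#' the pixel containing the station (no interpolation: the smoothing already
#' encodes the neighbourhood). When a predictor has several year-specific
#' layers, the layer whose year is nearest the station's `year` is used, ties
#' broken toward the earlier year.
#'
#' @param stack a `scaled_stack` from [build_scaled_stack()].
#' @param stations a station table (see [station_table()]).
#' @return data frame with `station_id` and one `"<predictor>_<scale>m"`
#'   column per layer; stations falling on nodata get `NA` (count reported
#'   via a message and the `"n_missing"` attribute) and are dropped by the
#'   fitting stages. Stations outside the raster extent are an error.
#' @export
extract_at_stations <- function(stack, stations) {
  stopifnot(inherits(stack, "scaled_stack"))
  ref <- stack$entries[[1L]]$raster
  cell <- point_to_cell(ref, stations$x, stations$y)
  if (anyNA(cell$row)) {
    bad <- stations$station_id[is.na(cell$row)]
    stop("stations outside raster extent: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(station_id = stations$station_id, stringsAsFactors = FALSE)
  for (nm in stack$names) {
    for (s in stack$scales) {
      layers <- stack_layers(stack, nm, s)
      col <- rep(NA_real_, nrow(stations))
      if (length(layers) == 1L) {
        col <- layers[[1L]]$raster$values[cbind(cell$row, cell$col)]
      } else {
        for (i in seq_len(nrow(stations))) {
          lyr <- stack_get(stack, nm, s, stations$year[i])
          col[i] <- lyr$values[cell$row[i], cell$col[i]]
        }
      }
      out[[sprintf("%s_%gm", nm, s)]] <- col
    }
  }
  n_missing <- sum(!stats::complete.cases(out))
  if (n_missing > 0)
    message(sprintf("extract_at_stations: %d station(s) fall on nodata in >=1 layer", n_missing))
  attr(out, "n_missing") <- n_missing
  out
}
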