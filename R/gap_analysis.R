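# Discretization of the suitability map and protected-area gap accounting.

suitability_class_labels <- function() c("Low", "Low-Med", "Med-High", "High")

#' Discretize a suitability raster into four equal-width classes
#'
#' Bins predicted probabilities into Low `[0, 0.25)`, Low-Med `[0.25, 0.5)`,
#' Med-High `[0.5, 0.75)` and High `[0.75, 1]` (intervals closed on the
#' left; the top bin also closed at 1 so every valid value is classified).
#' Nodata propagates.
#'
#' @param suitability probability raster with values in `[0, 1]` (tolerance
#'   `1e-9`; anything further outside is an error).
#' @return integer-valued raster (classes 1-4) of class `predictor_raster`,
#'   with a `"class_labels"` attribute.
#' @export
bin_suitability <- function(suitability) {
  stopifnot(inherits(suitability, "predictor_raster"))
  v <- suitability$values
  ok <- is.finite(v)
  if (any(v[ok] < -1e-9 | v[ok] > 1 + 1e-9))
    stop("suitability values outside [0, 1]", call. = FALSE)
  v[ok] <- pmin(pmax(v[ok], 0), 1)
  cls <- v
  cls[ok] <- findInterval(v[ok], c(0.25, 0.5, 0.75)) + 1
  out <- predictor_raster(cls, suitability$pixel_size, suitability$origin,
                          name = "suitability_class")
  attr(out, "class_labels") <- suitability_class_labels()
  out
}

#' Zonal areas of each suitability class
#'
#' Rasterizes each zone by pixel-center point-in-polygon membership and
#' accounts the area (km^2) of every suitability class inside it, with the
#' class proportions of each zone. Classes absent from a zone are reported
#' with zero area; a zone disjoint from the raster yields a zero row with a
#' warning.
#'
#' @param classes class raster from [bin_suitability()].
#' @param zones a [zone_set()] in the same planar CRS.
#' @return data frame of class `gap_table`: zone, protected, land_use,
#'   class, class_label, area_km2, prop_of_zone.
#' @export
zonal_area <- function(classes, zones) {
  stopifnot(inherits(classes, "predictor_raster"), inherits(zones, "zone_set"))
  ctr <- cell_centers(classes)
  vals <- classes$values
  valid <- is.finite(vals)
  px_km2 <- (classes$pixel_size / 1000)^2
  labels <- suitability_class_labels()
  rows <- lapply(zones, function(z) {
    inside <- points_in_zone(z, as.vector(ctr$x), as.vector(ctr$y))
    inside <- matrix(inside, nrow(vals), ncol(vals))
    sel <- inside & valid
    counts <- vapply(1:4, function(k) sum(vals[sel] == k), 0L)
    if (sum(counts) == 0)
      warning("zone '", z$name, "' contains no valid raster cells", call. = FALSE)
    data.frame(zone = z$name, protected = z$protected, land_use = z$land_use,
               class = 1:4, class_label = labels,
               area_km2 = counts * px_km2,
               prop_of_zone = if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, 4),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gap_table", "data.frame")
  attr(out, "pixel_km2") <- px_km2
  out
}

#' Protection summary of the suitability classes
#'
#' Computes, per suitability class, the area inside the union of protected
#' zones, the area outside it, and the fraction protected; plus the class
#' composition of the protected network. Working from the union mask (rather
#' than summing per-zone areas) keeps overlapping protected polygons from
#' being double-counted.
#'
#' @param classes class raster from [bin_suitability()].
#' @param zones a [zone_set()]; zones flagged `protected` form the network.
#' @return data frame: class, class_label, protected_km2, unprotected_km2,
#'   fraction_protected (`NA` for classes with zero total area), and
#'   prop_of_protected (class composition of the network).
#' @export
protection_summary <- function(classes, zones) {
  stopifnot(inherits(classes, "predictor_raster"), inherits(zones, "zone_set"))
  ctr <- cell_centers(classes)
  vals <- classes$values
  valid <- is.finite(vals)
  px_km2 <- (classes$pixel_size / 1000)^2
  prot <- matrix(FALSE, nrow(vals), ncol(vals))
  for (z in zones) {
    if (!z$protected) next
    prot <- prot | matrix(points_in_zone(z, as.vector(ctr$x), as.vector(ctr$y)),
                          nrow(vals), ncol(vals))
  }
  tab <- do.call(rbind, lapply(1:4, function(k) {
    ink <- valid & vals == k
    p <- sum(ink & prot); u <- sum(ink & !prot)
    data.frame(class = k, class_label = suitability_class_labels()[k],
               protected_km2 = p * px_km2, unprotected_km2 = u * px_km2,
               fraction_protected = if (p + u > 0) p / (p + u) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tot_prot <- sum(tab$protected_km2)
  tab$prop_of_protected <- if (tot_prot > 0) tab$protected_km2 / tot_prot else NA_real_
  rownames(tab) <- NULL
  tab
}
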