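#' Zone polygon sets
#'
#' A `zone_set` is a list of named polygon zones (protected areas, land-use
#' classes) in the same planar CRS as the rasters. Each zone is a list with
#' `name`, `protected` (logical), `land_use` (character or `NA`) and `rings`
#' (a list of closed two-column x/y matrices; additional rings are holes,
#' resolved by the even-odd rule).
#'
#' @param zones list of zone lists as described above.
#' @return object of class `zone_set`.
#' @export
zone_set <- function(zones) {
  for (z in zones) {
    stopifnot(is.character(z$name), is.logical(z$protected), length(z$rings) >= 1)
    for (rg in z$rings) stopifnot(is.matrix(rg), ncol(rg) == 2, nrow(rg) >= 4)
  }
  structure(zones, class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (%d protected)\n",
              length(x), sum(vapply(x, `[[`, TRUE, "protected"))))
  for (z in x)
    cat(sprintf("  %s%s%s\n", z$name, if (z$protected) " [protected]" else "",
                if (is.na(z$land_use)) "" else paste0(" <", z$land_use, ">")))
  invisible(x)
}

# TRUE/FALSE for each (x, y) point inside the zone (even-odd over all rings).
points_in_zone <- function(zone, x, y) {
  bnd <- do.call(rbind, lapply(seq_along(zone$rings), function(i) {
    rg <- zone$rings[[i]]
    if (i == 1) rg else rbind(c(NA, NA), rg)
  }))
  mgcv::in.out(bnd, cbind(x, y))
}

#' Read / write zone polygons as GeoJSON
#'
#' Zones round-trip as a GeoJSON `FeatureCollection` of `Polygon` /
#' `MultiPolygon` features with `name`, `protected` and `land_use`
#' properties. Coordinates are planar meters (no CRS transformation is
#' performed).
#'
#' @param zones a [zone_set()].
#' @param path file path.
#' @return `write_zones_geojson()` returns `path` invisibly;
#'   `read_zones_geojson()` returns a `zone_set`.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    coords <- lapply(z$rings, function(rg) {
      rg <- unname(rg)
      if (!all(rg[1, ] == rg[nrow(rg), ])) rg <- rbind(rg, rg[1, ])
      lapply(seq_len(nrow(rg)), function(i) c(rg[i, 1], rg[i, 2]))
    })
    list(type = "Feature",
         properties = list(name = z$name, protected = z$protected,
                           land_use = z$land_use),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_zones_geojson
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  zones <- lapply(gj$features, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    list(name = as.character(f$properties$name),
         protected = isTRUE(f$properties$protected),
         land_use = if (is.null(f$properties$land_use)) NA_character_
                    else as.character(f$properties$land_use),
         rings = rings)
  })
  zone_set(zones)
}
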