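#' In-memory single-band raster in a projected planar CRS
#'
#' The package's raster container: a numeric matrix plus the georeferencing
#' needed for metric neighbourhood operations. Coordinates are planar meters;
#' pixels are addressed row-major from the top-left corner, so row 1 is the
#' northernmost row. `NA` cells are nodata.
#'
#' @param values numeric matrix (rows = north to south, cols = west to east);
#'   `NA` marks nodata.
#' @param pixel_size cell edge length in meters (> 0).
#' @param origin map coordinates `c(x, y)` of the raster's top-left corner
#'   (west edge, north edge).
#' @param name layer name.
#' @param year optional acquisition year (used for year-matched extraction).
#' @return an object of class `predictor_raster`.
#' @seealso [focal_smooth()], [extract_at_stations()], [write_asc()]
#' @export
predictor_raster <- function(values, pixel_size, origin = c(0, nrow(values) * pixel_size),
                             name = "layer", year = NA_integer_) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0)
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (meters)", call. = FALSE)
  structure(
    list(name = as.character(name), year = as.integer(year),
         values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin)),
    class = "predictor_raster"
  )
}

#' @export
print.predictor_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<predictor_raster> %s%s: %d x %d @ %gm, origin (%g, %g)\n",
              x$name, if (is.na(x$year)) "" else paste0(" [", x$year, "]"),
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g, %d nodata cells\n",
                min(v), max(v), mean(v), sum(!is.finite(x$values))))
  invisible(x)
}

#' Raster extent as (xmin, xmax, ymin, ymax)
#' @param r a `predictor_raster`.
#' @return numeric length-4 vector.
#' @export
raster_extent <- function(r) {
  c(xmin = r$origin[1], xmax = r$origin[1] + ncol(r$values) * r$pixel_size,
    ymin = r$origin[2] - nrow(r$values) * r$pixel_size, ymax = r$origin[2])
}

# Map coordinates of every cell center, as matrices aligned with $values.
cell_centers <- function(r) {
  px <- r$pixel_size
  xs <- r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * px
  ys <- r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * px
  list(x = matrix(xs, nrow(r$values), ncol(r$values), byrow = TRUE),
       y = matrix(ys, nrow(r$values), ncol(r$values)))
}

# Row/col of the pixel containing each point, with half-open pixel intervals
# [x0, x0 + px) in x and (y0 - px, y0] in y (top-left anchored). Points
# outside the extent get NA.
point_to_cell <- function(r, x, y) {
  px <- r$pixel_size
  col <- floor((x - r$origin[1]) / px) + 1L
  row <- floor((r$origin[2] - y) / px) + 1L
  # the top edge y == origin_y belongs to row 1
  row[r$origin[2] - y == 0] <- 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read / write rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`), readable by GDAL and
#' QGIS. Nodata cells are stored as `-9999` and round-trip to `NA`.
#'
#' @param r a `predictor_raster`.
#' @param path file path.
#' @param name,year metadata attached to the raster on read (the `.asc`
#'   header carries none).
#' @return `write_asc()` returns `path` invisibly; `read_asc()` returns a
#'   `predictor_raster`.
#' @export
write_asc <- function(r, path) {
  stopifnot(inherits(r, "predictor_raster"))
  ext <- raster_extent(r)
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", ext["xmin"]),
    sprintf("yllcorner %.10g", ext["ymin"]),
    sprintf("cellsize %.10g", r$pixel_size),
    "NODATA_value -9999"
  )
  v <- r$values
  v[!is.finite(v)] <- -9999
  body <- apply(v, 1, function(row) paste(formatC(row, format = "g", digits = 9), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path, name = sub("\\.asc$", "", basename(path)), year = NA_integer_) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals[vals == nodata] <- NA_real_
  px <- hdr[["cellsize"]]
  predictor_raster(vals, px,
                   origin = c(hdr[["xllcorner"]], hdr[["yllcorner"]] + nrow(vals) * px),
                   name = name, year = year)
}
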