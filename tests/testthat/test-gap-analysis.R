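rect_ring <- function(x0, y0, w, h) {
  cbind(x = c(x0, x0 + w, x0 + w, x0, x0), y = c(y0, y0, y0 + h, y0 + h, y0))
}

test_that("suitability binning uses closed-left quarters with a closed top bin", {
  r <- predictor_raster(matrix(c(0.1, 0.3, 0.6, 0.9), 2, 2), 250)
  cls <- bin_suitability(r)
  expect_equal(as.vector(cls$values), c(1, 2, 3, 4))

  edges <- predictor_raster(matrix(c(0, 0.25, 0.5, 0.75, 1, NA), 2, 3), 250)
  ce <- bin_suitability(edges)
  expect_equal(as.vector(ce$values), c(1, 2, 3, 4, 4, NA))  # 0.25 -> Low-Med; 1.0 -> High
  expect_equal(attr(ce, "class_labels"), c("Low", "Low-Med", "Med-High", "High"))

  expect_error(bin_suitability(predictor_raster(matrix(c(0.2, 1.2), 1, 2), 250)),
               "outside")
  # within-tolerance overshoot is clamped, not rejected
  expect_equal(as.vector(bin_suitability(
    predictor_raster(matrix(1 + 1e-12, 1, 1), 250))$values), 4)
})

test_that("zonal areas count pixel centers and normalize per zone", {
  # 4x4 raster of 250 m pixels, uniform class High
  r <- predictor_raster(matrix(0.9, 4, 4), 250)
  cls <- bin_suitability(r)
  whole <- zone_set(list(list(name = "all", protected = TRUE, land_use = NA_character_,
                              rings = list(rect_ring(0, 0, 1000, 1000)))))
  gap <- zonal_area(cls, whole)
  expect_equal(gap$prop_of_zone[gap$class == 4], 1)
  expect_equal(sum(gap$area_km2), 16 * 0.0625)

  # zone covering the left two columns: 8 pixels x 0.0625 km2 = 0.5 km2
  left <- zone_set(list(list(name = "left", protected = FALSE, land_use = "paddy",
                             rings = list(rect_ring(0, 0, 500, 1000)))))
  gl <- zonal_area(cls, left)
  expect_equal(sum(gl$area_km2), 0.5)

  # mixed classes: proportions sum to 1 within every non-empty zone
  vm <- matrix(runif(64), 8, 8)
  gz <- zonal_area(bin_suitability(predictor_raster(vm, 250)),
                   zone_set(list(
                     list(name = "a", protected = TRUE, land_use = NA_character_,
                          rings = list(rect_ring(0, 0, 1200, 2000))),
                     list(name = "b", protected = FALSE, land_use = NA_character_,
                          rings = list(rect_ring(1200, 0, 800, 2000))))))
  for (z in c("a", "b"))
    expect_equal(sum(gz$prop_of_zone[gz$zone == z]), 1, tolerance = 1e-9)
  # the two zones partition the raster: areas add to the full valid area
  expect_equal(sum(gz$area_km2), 64 * 0.0625, tolerance = 1e-9)

  expect_warning(zonal_area(cls, zone_set(list(
    list(name = "far", protected = FALSE, land_use = NA_character_,
         rings = list(rect_ring(9000, 9000, 100, 100)))))), "no valid raster cells")
})

test_that("zonal accounting commutes with cropping to the zone's bounding box", {
  set.seed(90)
  v <- matrix(runif(400), 20, 20)
  r <- predictor_raster(v, 250)
  z <- zone_set(list(list(name = "z", protected = FALSE, land_use = NA_character_,
                          rings = list(rect_ring(500, 750, 2000, 1500)))))
  full <- zonal_area(bin_suitability(r), z)
  # crop to columns 3..10, rows 12..17 (the zone's bounding box)
  sub <- predictor_raster(v[12:17, 3:10], 250, origin = c(500, 2250))
  cropped <- zonal_area(bin_suitability(sub), z)
  expect_equal(full$area_km2, cropped$area_km2)
})

test_that("protection summary reports per-class fractions from the zone union", {
  # High class in the left 20 columns; protected rectangle covers 15% of it
  v <- matrix(0.3, 100, 100)
  v[, 1:20] <- 0.9
  cls <- bin_suitability(predictor_raster(v, 250))
  # High cells: 100 rows x 20 cols = 2000; protect rows 1..15 of those cols = 300
  zones <- zone_set(list(
    list(name = "PA", protected = TRUE, land_use = NA_character_,
         rings = list(rect_ring(0, 25000 - 15 * 250, 20 * 250, 15 * 250))),
    list(name = "elsewhere", protected = FALSE, land_use = "community mosaic",
         rings = list(rect_ring(20 * 250, 0, 80 * 250, 25000)))))
  ps <- protection_summary(cls, zones)
  expect_equal(ps$fraction_protected[ps$class == 4], 0.15, tolerance = 1e-9)
  expect_equal(ps$protected_km2[ps$class == 4], 300 * 0.0625)
  expect_equal(ps$fraction_protected[ps$class == 2], 0)   # Low-Med never protected
  # classes with zero total area report NA, not 0
  expect_true(is.na(ps$fraction_protected[ps$class == 1]))
  expect_true(is.na(ps$fraction_protected[ps$class == 3]))
  # composition of the protected network sums to 1
  expect_equal(sum(ps$prop_of_protected, na.rm = TRUE), 1)

  # everything protected -> fraction 1 for every non-empty class
  allz <- zone_set(list(list(name = "all", protected = TRUE, land_use = NA_character_,
                             rings = list(rect_ring(0, 0, 25000, 25000)))))
  psa <- protection_summary(cls, allz)
  expect_true(all(psa$fraction_protected[c(2, 4)] == 1))
})

test_that("zone sets round-trip through GeoJSON", {
  zones <- zone_set(list(
    list(name = "PA-1", protected = TRUE, land_use = NA_character_,
         rings = list(rect_ring(0, 0, 1000, 1000),
                      rect_ring(200, 200, 100, 100))),   # hole
    list(name = "paddy-west", protected = FALSE, land_use = "paddy",
         rings = list(rect_ring(3000, 0, 500, 800)))))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones_geojson(zones, path)
  rt <- read_zones_geojson(path)
  expect_equal(length(rt), 2)
  expect_equal(rt[[1]]$name, "PA-1")
  expect_true(rt[[1]]$protected)
  expect_false(rt[[2]]$protected)
  expect_equal(rt[[2]]$land_use, "paddy")
  expect_equal(length(rt[[1]]$rings), 2)
  expect_equal(unname(rt[[1]]$rings[[1]]), unname(zones[[1]]$rings[[1]]))
  # hole semantics survive the round trip
  expect_false(points_in_zone(rt[[1]], 250, 250))
  expect_true(points_in_zone(rt[[1]], 600, 600))
})
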