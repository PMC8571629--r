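test_that("rasterization reproduces single points and averages shared cells", {
  pts <- tibble::tibble(x = c(8, 24, 40), y = c(8, 8, 24),
                        depth = c(1, 2, 3))
  g <- rasterize_points(pts, cell_size = 16, fill_radius = 0)
  expect_equal(g$depth[match(paste(c(8, 24, 40), c(8, 8, 24)),
                             paste(g$x, g$y))], c(1, 2, 3))
  two <- tibble::tibble(x = c(3, 5), y = c(3, 5), depth = c(2, 4))
  g2 <- rasterize_points(two, cell_size = 16, fill_radius = 0)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$depth, 3)
  expect_error(rasterize_points(tibble::tibble(x = numeric(), y = numeric(),
                                               depth = numeric())),
               class = "lakesav_error_domain")
})

test_that("grid snapping puts cell edges on multiples of the cell size", {
  pts <- tibble::tibble(x = c(13.7, 91.2), y = c(21.9, 55.1), depth = c(1, 2))
  g <- rasterize_points(pts, cell_size = 16)
  expect_equal(grid_origin(g) %% 16, c(0, 0))
  expect_equal((g$x - 8) %% 16, rep(0, nrow(g)))
})

test_that("rasterization matches the brute-force binning oracle", {
  withr::with_seed(31, {
    for (i in 1:40) {
      n <- sample(5:120, 1)
      cs <- sample(c(4, 8, 16), 1)
      pts <- tibble::tibble(x = runif(n, -50, 180), y = runif(n, -30, 140),
                            value = rnorm(n))
      g <- rasterize_points(pts, cell_size = cs, fill_radius = 0)
      expect_equal(grid_layer_matrix(g, "value"), brute_rasterize(pts, cs),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("neighbour fill completes isolated gaps but not open water", {
  # 3x3 block of points with the centre missing: centre fills with the mean
  pts <- tidyr::expand_grid(x = c(8, 24, 40), y = c(8, 24, 40)) |>
    dplyr::mutate(depth = 2) |>
    dplyr::filter(!(x == 24 & y == 24))
  g <- rasterize_points(pts, cell_size = 16, fill_radius = 1)
  expect_equal(g$depth[g$x == 24 & g$y == 24], 2)
})

test_that("distance surface is the per-cell hypotenuse", {
  g <- lake_grid_from_matrix(matrix(1, 20, 20), cell_size = 16)
  outlet <- c(8, 8)  # centre of the lower-left cell
  d <- distance_to_outlet(g, outlet)
  expect_equal(d$distance_km[d$x == 8 & d$y == 8], 0)
  # a cell 3000 m due north would be off this grid; use a bigger one
  big <- lake_grid_from_matrix(matrix(1, 400, 5), cell_size = 10)
  db <- distance_to_outlet(big, c(5, 5))
  expect_equal(db$distance_km[db$x == 5 & db$y == 3005], 3.0)
  oracle <- sqrt((g$x - outlet[1])^2 + (g$y - outlet[2])^2) / 1000
  expect_lt(max(abs(d$distance_km - oracle)), 1e-9)
  expect_error(distance_to_outlet(g, c(-5, 8)), class = "lakesav_error_domain")
})

test_that("predicted Secchi surface applies the linear clarity model", {
  g <- lake_grid_from_matrix(matrix(0, 5, 5), cell_size = 1000,
                             layer = "distance_km")
  g$distance_km <- seq(0, by = 0.5, length.out = 25)
  s <- predict_secchi_surface(g, secchi_model())
  expect_equal(round(s$secchi[g$distance_km == 0], 1), 0.7)
  expect_equal(s$secchi[g$distance_km == 10], 0.073 * 10 + 0.69)
  expect_equal(round(s$secchi[g$distance_km == 10], 2), 1.42)
  flat <- predict_secchi_surface(g, secchi_model(slope = 0, intercept = 1.1))
  expect_true(all(flat$secchi == 1.1))
  expect_error(predict_secchi_surface(g, secchi_model(slope = -1, intercept = 0.5)),
               "non-positive")
})

test_that("bottom-light surface equals the scalar optics model per cell", {
  depth <- matrix(c(0, 1, 2, NA), 2, 2)
  b <- lake_grid_from_matrix(depth, layer = "depth", cell_size = 16)
  s <- lake_grid_from_matrix(matrix(0.7, 2, 2), layer = "secchi", cell_size = 16)
  l <- light_at_bottom_surface(b, s)
  expect_equal(l$light[b$depth == 0 & !is.na(b$depth)], 1.0)
  expect_equal(l$light[!is.na(b$depth) & b$depth == 2],
               exp(-1.7 * 2 / 0.7), tolerance = 1e-12)
  expect_equal(round(l$light[!is.na(b$depth) & b$depth == 2], 4), 0.0078)
  expect_true(is.na(l$light[is.na(b$depth)]))
  expect_equal(l$light, percent_irradiance(b$depth, s$secchi))
  s_bad <- lake_grid_from_matrix(matrix(0.7, 3, 2), layer = "secchi",
                                 cell_size = 16)
  expect_error(light_at_bottom_surface(b, s_bad),
               class = "lakesav_error_alignment")
})

test_that("class boundaries follow the printed half-open intervals", {
  expect_equal(classify_light(c(0.149, 0.15, 0.249, 0.25, 0, 1)),
               c(1L, 2L, 2L, 3L, 1L, 3L))
  expect_equal(classify_biovolume(c(9.9, 10, 24.9, 25, 0, 100)),
               c(1L, 2L, 2L, 3L, 1L, 3L))
  expect_error(classify_light(1.2), class = "lakesav_error_domain")
  expect_error(classify_biovolume(-3), class = "lakesav_error_domain")
})

test_that("class intervals partition their domains", {
  withr::with_seed(5, {
    lv <- runif(500)
    bv <- runif(500, 0, 100)
  })
  lc <- classify_light(lv); bc <- classify_biovolume(bv)
  expect_true(all(lc %in% 1:3))
  expect_true(all(bc %in% 1:3))
  # each value lands in exactly the interval containing it
  expect_identical(lc, 1L + (lv >= 0.15) + (lv >= 0.25))
  expect_identical(bc, 1L + (bv >= 10) + (bv >= 25))
})

test_that("classification commutes with masking", {
  cfg <- small_config(seed = 2)
  b <- simulate_bathymetry(cfg)
  s <- predict_secchi_surface(distance_to_outlet(b, cfg$outlet_xy), secchi_model())
  l <- light_at_bottom_surface(b, s)
  cls_then_mask <- classify_light(l)$class
  cls_then_mask[is.na(b$depth)] <- NA_integer_
  l_masked <- l
  l_masked$light[is.na(b$depth)] <- NA_real_
  mask_then_cls <- classify_light(l_masked)$class
  expect_identical(cls_then_mask, mask_then_cls)
})

test_that("vegetated-area fraction counts classes 2-3 over wet cells", {
  all1 <- lake_grid_from_matrix(matrix(1L, 4, 4), layer = "class")
  expect_equal(sav_area_fraction(all1)$fraction, 0)
  half <- lake_grid_from_matrix(matrix(c(1L, 2L), 4, 4), layer = "class")
  expect_equal(sav_area_fraction(half)$fraction, 0.5)
  withna <- lake_grid_from_matrix(matrix(c(3L, NA), 4, 4), layer = "class")
  expect_equal(sav_area_fraction(withna)$fraction, 1)
  expect_equal(sav_area_fraction(withna)$n_wet, 8)
})

test_that("morphometry arithmetic: area, volume, hypsography", {
  b <- lake_grid_from_matrix(matrix(2, 100, 100), cell_size = 16)
  m <- morphometry(b)
  expect_equal(m$area_m2, 100 * 100 * 256)
  expect_equal(m$area_ha, 256)
  expect_equal(m$volume_m3, 5.12e6)
  b2 <- lake_grid_from_matrix(matrix(4, 100, 100), cell_size = 16)
  m2 <- morphometry(b2)
  expect_equal(m2$volume_m3, 2 * m$volume_m3)
  expect_equal(m2$area_m2, m$area_m2)
  expect_equal(m$hypsography$fraction_shallower[m$hypsography$depth_m == 0], 0)
  expect_equal(max(m$hypsography$fraction_shallower), 1)
})

test_that("morphometry matches per-cell brute-force summation", {
  withr::with_seed(17, {
    for (i in 1:30) {
      nx <- sample(4:20, 1); ny <- sample(4:20, 1)
      depth <- matrix(ifelse(runif(nx * ny) < 0.3, NA, runif(nx * ny, 0, 6)),
                      ny, nx)
      if (all(is.na(depth))) depth[1] <- 1
      g <- lake_grid_from_matrix(depth, cell_size = 16)
      m <- morphometry(g)
      ref <- brute_morphometry(g$depth, 16)
      expect_equal(m$area_m2, unname(ref["area_m2"]))
      expect_equal(m$volume_m3, unname(ref["volume_m3"]), tolerance = 1e-12)
    }
  })
})

test_that("zero drawdown reproduces the hypsographic fractions", {
  cfg <- small_config(seed = 8)
  b <- simulate_bathymetry(cfg)
  dd <- drawdown_simulation(b, drawdowns = 0)
  expect_equal(dd$fraction_dried, 0)
  hyps <- morphometry(b)$hypsography
  expect_equal(dd$fraction_lt_1m,
               hyps$fraction_shallower[hyps$depth_m == 1], tolerance = 1e-12)
  expect_equal(dd$fraction_lt_2m,
               hyps$fraction_shallower[hyps$depth_m == 2], tolerance = 1e-12)
  expect_equal(dd$fraction_lt_2m + dd$fraction_ge_2m, 1)
})

test_that("uniform lakes dry out completely at their depth", {
  b <- lake_grid_from_matrix(matrix(3, 10, 10), cell_size = 16)
  dd <- drawdown_simulation(b, drawdowns = 3)
  expect_equal(dd$fraction_dried, 1)
  expect_equal(dd$fraction_ge_2m, 0)
  expect_error(drawdown_simulation(b, drawdowns = -1),
               class = "lakesav_error_domain")
})

test_that("drawdown fractions are monotone and partition the wet area", {
  withr::with_seed(23, {
    for (i in 1:20) {
      depth <- matrix(ifelse(runif(100) < 0.2, NA, runif(100, 0.1, 8)), 10, 10)
      if (all(is.na(depth))) depth[1] <- 2
      g <- lake_grid_from_matrix(depth, cell_size = 16)
      dd <- drawdown_simulation(g, drawdowns = sort(runif(5, 0, 6)))
      expect_true(all(diff(dd$fraction_dried) >= 0))
      expect_true(all(diff(dd$fraction_ge_2m) <= 0))
      expect_true(all(dd$fraction_lt_1m <= dd$fraction_lt_2m + 1e-12))
      expect_equal(dd$fraction_dried + dd$fraction_lt_2m + dd$fraction_ge_2m,
                   rep(1, 5), tolerance = 1e-12)
    }
  })
})
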