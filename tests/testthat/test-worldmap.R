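test_that("identical scenario forests give a CV of zero everywhere", {
  world <- gen_stock_records(default_truth(), small_world(), 200, seed = 3)
  world$coverage$values[!is.na(world$coverage$values)] <- 120
  ens <- run_simulations(world$records, world, "biomass", "macrofauna",
                         n_trees = 40, seed = 5)
  pg <- grid_predict(ens, world)
  cv <- pg$cv[!is.na(pg$cv)]
  expect_gt(length(cv), 100)
  expect_true(all(cv == 0))
})

test_that("a chlorophyll-driven truth yields a chlorophyll-correlated map", {
  world <- small_world()
  tr <- default_truth(sigma = 0.1, pred_effect_scale = 0)
  tr$coefs <- tr$coefs[tr$coefs$class == "meiofauna" & tr$coefs$response == "biomass", ]
  tr$coefs$b <- 0; tr$coefs$c_lat <- 0; tr$coefs$c_lon <- 0
  tr$pred_effects <- list(meiofauna = c(chl.mean = 1))
  world <- gen_stock_records(tr, world, 400, seed = 7)
  ens <- run_simulations(world$records, world, "biomass", "meiofauna",
                         n_trees = 60, seed = 9)
  pg <- grid_predict(ens, world)
  ok <- !is.na(pg$mean) & !is.na(world$grids[["chl.mean"]]$values)
  rho <- cor(pg$mean[ok], world$grids[["chl.mean"]]$values[ok], method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("class combination back-transforms and sums in linear space", {
  v2 <- matrix(2, 10, 20)          # log10 = 2 -> 100 mg C m-2
  v2[1, 1] <- NA
  mk_pg <- function(vals) structure(list(class = "x", response = "biomass",
    lat = benthicstocks:::grid_centers(10, -90, 90),
    lon = benthicstocks:::grid_centers(20, -180, 180),
    mean = vals, sd = vals * 0, cv = vals * 0, depth = vals * 0 + 1000),
    class = "prediction_grid")
  total <- combine_classes(list(mk_pg(v2), mk_pg(v2)))
  expect_equal(total$values[5, 5], 200)
  expect_true(is.na(total$values[1, 1]))           # strict NA policy
  lenient <- combine_classes(list(mk_pg(v2), mk_pg(v2)), strict = FALSE)
  expect_equal(lenient$values[1, 1], NA_real_)     # both classes NA there
  one <- mk_pg(v2); one$mean[1, 1] <- 2
  lenient2 <- combine_classes(list(one, mk_pg(v2)), strict = FALSE)
  expect_equal(lenient2$values[1, 1], 100)    # partial sum over available classes
  bad <- structure(list(values = matrix(1, 5, 5), lat = 1:5, lon = 1:5),
                   class = "world_grid")
  expect_error(combine_classes(list(mk_pg(v2), bad)), "lattice")
})

test_that("IDW reproduces the hand-computed two-neighbor case and exact hits", {
  # two ocean cells on the equator-adjacent row: lon 0.5 (value 0) and
  # lon 4.5 (value 10); with factor 5 a fine center falls exactly on
  # lon 1.5 at the coarse row latitude: distances 1 and 3 degrees
  v <- matrix(NA_real_, 180, 360)
  i <- 91                     # lat center +0.5
  j1 <- which.min(abs(benthicstocks:::grid_centers(360, -180, 180) - 0.5))
  j2 <- which.min(abs(benthicstocks:::grid_centers(360, -180, 180) - 4.5))
  v[i, j1] <- 0; v[i, j2] <- 10
  g <- world_grid(v)
  fine <- idw_interpolate(g, factor = 5, power = 2, n_neighbors = 2,
                          max_radius = 8, mask_land = FALSE)
  fi <- which.min(abs(fine$lat - 0.5))
  fj <- which.min(abs(fine$lon - 1.5))
  expect_equal(fine$lat[fi], 0.5, tolerance = 1e-12)
  expect_equal(fine$lon[fj], 1.5, tolerance = 1e-12)
  expect_equal(fine$values[fi, fj], (0 * 1 + 10 * 1 / 9) / (1 + 1 / 9),
               tolerance = 1e-9)
  # exact hit: the fine center coinciding with an ocean coarse center
  fj1 <- which.min(abs(fine$lon - 0.5))
  expect_equal(fine$values[fi, fj1], 0, tolerance = 1e-12)
})

test_that("IDW preserves constant fields, the value range, and the land mask", {
  world <- small_world()
  v <- world$bathymetry$values
  const <- world_grid(ifelse(is.na(v), NA_real_, 7))
  fine <- idw_interpolate(const, factor = 4, max_radius = 6)
  got <- fine$values[!is.na(fine$values)]
  expect_true(all(abs(got - 7) < 1e-12))
  # land mask survives at coarse resolution
  land_cell <- which(is.na(v), arr.ind = TRUE)[1, ]
  block_i <- (land_cell[1] - 1) * 4 + 1:4
  block_j <- (land_cell[2] - 1) * 4 + 1:4
  expect_true(all(is.na(fine$values[block_i, block_j])))
  # range containment on a real field
  g <- world_grid(ifelse(is.na(v), NA_real_, log10(v)))
  f2 <- idw_interpolate(g, factor = 3, max_radius = 6)
  expect_gte(min(f2$values, na.rm = TRUE), min(g$values, na.rm = TRUE) - 1e-9)
  expect_lte(max(f2$values, na.rm = TRUE), max(g$values, na.rm = TRUE) + 1e-9)
})

test_that("Jenks breaks match the exhaustive-partition oracle", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), c(3, 12))
  x <- c(4, 1, 9, 2, 8, 3)
  expect_equal(sort(jenks_breaks(x, length(unique(x)))), sort(unique(x)))
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(6:12, 1); k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    got <- jenks_breaks(x, k)
    oracle <- jenks_oracle(x, k)
    # compare achieved within-class SSD (break positions can tie)
    ssd_of <- function(breaks) {
      xs <- sort(x)
      cls <- findInterval(xs, c(-Inf, breaks[-length(breaks)] + 1e-9)) + 1
      sum(tapply(xs, cls, function(z) sum((z - mean(z))^2)))
    }
    expect_equal(ssd_of(got), oracle$ssd, tolerance = 1e-9)
  }
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
  expect_error(jenks_breaks(1:5, 1), "at least 2")
})

test_that("the global integral matches the closed-form spherical oracle", {
  # uniform 1 mg C m-2 over a fully oceanic globe
  ocean <- world_grid(matrix(1, 180, 360), "uniform", "mg C m-2")
  got <- global_integral(ocean)
  R <- 6371
  spherical <- 1 * (4 * pi * R^2) * 1e6 / 1e15     # mg over the sphere -> Mt
  expect_lt(abs(got - spherical) / spherical, 0.005)
  # single equatorial cell
  single <- world_grid(matrix(NA_real_, 180, 360))
  single$values[91, 180] <- 1
  expect_equal(global_integral(single),
               12343 * cos(0.5 * pi / 180) * 1e6 / 1e15, tolerance = 1e-12)
  # empty ocean mask and negative values
  expect_equal(global_integral(world_grid(matrix(NA_real_, 18, 36))), 0)
  neg <- world_grid(matrix(-1, 4, 8))
  expect_error(global_integral(neg), "negative")
})

test_that("zonal integrals bin correctly and conserve the global integral", {
  world <- small_world()
  v <- world$bathymetry$values
  biom <- world_grid(ifelse(is.na(v), NA_real_, 500 * 10^(-v / 3000)))
  gi <- global_integral(biom)
  for (mode in c("depth_100m", "lat_2deg")) {
    z <- zonal_integrals(biom, world$bathymetry, mode)
    expect_lt(abs(sum(z$mass_Mt) - gi) / gi, 1e-9)
    expect_lt(abs(sum(z$area_km2) - benthicstocks:::ocean_area_km2(biom)) /
                sum(z$area_km2), 1e-9)
  }
  # all cells at 150 m fall into the [100, 200) bin
  flat <- gen_bathymetry(2, 18, 36, constant_depth = 150)
  b2 <- world_grid(ifelse(is.na(flat$values), NA_real_, 10))
  z <- zonal_integrals(b2, flat, "depth_100m")
  expect_equal(nrow(z), 1)
  expect_equal(z$bin_lo, 100); expect_equal(z$bin_hi, 200)
})

test_that("residence time is mass over net flux", {
  expect_equal(residence_time(0, 3.8, 0.8), 0)
  expect_equal(residence_time(3.8, 3.8, 0), 1)
  expect_error(residence_time(100, 0.8, 0.82), "net flux")
  expect_error(residence_time(100, 1, -0.1), "burial")
})

test_that("prediction tables round-trip through the 1-degree CSV layout", {
  world <- gen_stock_records(default_truth(), small_world(), 150, seed = 3)
  ens <- run_simulations(world$records, world, "biomass", "macrofauna",
                         n_trees = 30, seed = 5)
  pg <- grid_predict(ens, world)
  path <- withr::local_tempfile(fileext = ".csv")
  write_prediction_csv(list(macrofauna = pg), path)
  back <- read_prediction_csv(path, n_lat = 36, n_lon = 72)
  expect_named(back$classes, "macrofauna")
  ok <- !is.na(pg$mean)
  expect_equal(back$classes$macrofauna$values[ok], pg$mean[ok], tolerance = 1e-9)
  expect_equal(back$depth$values[ok], pg$depth[ok], tolerance = 1e-9)
  # back-transform + integral of the file equals the integral of the object
  lin_file <- world_grid(10^back$classes$macrofauna$values)
  lin_obj <- world_grid(10^pg$mean)
  expect_equal(global_integral(lin_file), global_integral(lin_obj),
               tolerance = 1e-9)
})
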