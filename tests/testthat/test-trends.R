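# fixture with depth exactly orthogonal (in sample) to latitude and longitude
orthogonal_design <- function(n = 200, seed = 1) {
  set.seed(seed)
  lat <- runif(n, -70, 70); lon <- runif(n, -179, 179)
  d0 <- runif(n, 10, 5000)
  Z <- cbind(1, lat, lon)
  depth <- as.numeric(d0 - Z %*% solve(crossprod(Z), crossprod(Z, d0))) + mean(d0)
  list(lat = lat, lon = lon, depth = depth)
}

test_that("partial regression recovers a noise-free depth law exactly in an orthogonal design", {
  dsn <- orthogonal_design()
  y <- 3.05 - 5.15e-4 * dsn$depth
  fit <- suppressWarnings(partial_regression(y, dsn$lat, dsn$lon, dsn$depth))
  expect_equal(fit$slope, -5.15e-4, tolerance = 1e-9)
  expect_equal(fit$intercept, 3.05, tolerance = 1e-7)
  # and equals the plain OLS-on-depth slope
  plain <- unname(coef(lm(y ~ dsn$depth))[2])
  expect_equal(fit$slope, plain, tolerance = 1e-10)
})

test_that("two-stage slope matches the closed-form projection oracle on correlated designs", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 150
    lat <- runif(n, -70, 70)
    depth <- 2500 + 20 * lat + rnorm(n, 0, 1200)   # depth correlated with lat
    lon <- runif(n, -179, 179)
    y <- 2 - 4e-4 * depth + 0.01 * lat + rnorm(n, 0, 0.3)
    fit <- partial_regression(y, lat, lon, depth)
    expect_equal(fit$slope, partial_slope_oracle(y, lat, lon, depth),
                 tolerance = 1e-9)
    # in a correlated design the two-stage slope differs from plain OLS
    plain <- unname(coef(lm(y ~ depth))[2])
    expect_gt(abs(fit$slope - plain), 1e-8)
  }
})

test_that("detrending is invariant to translating latitude or longitude", {
  dsn <- orthogonal_design(seed = 2)
  set.seed(2)
  y <- 2.5 - 3e-4 * dsn$depth + 0.004 * dsn$lat + rnorm(200, 0, 0.2)
  f0 <- partial_regression(y, dsn$lat, dsn$lon, dsn$depth)
  f1 <- partial_regression(y, dsn$lat + 10, dsn$lon + 20, dsn$depth)
  expect_equal(f0$slope, f1$slope, tolerance = 1e-12)
})

test_that("depth-independent responses are declared non-significant", {
  set.seed(5)
  n <- 500
  dsn <- orthogonal_design(n, seed = 5)
  y <- 2.4 + rnorm(n, 0, 0.5)          # the bacterial situation: no depth trend
  fit <- partial_regression(y, dsn$lat, dsn$lon, dsn$depth)
  expect_false(fit$significant)
  expect_gt(fit$p, 0.001)
})

test_that("shuffling depth against the response gives a null slope", {
  set.seed(6)
  n <- 300
  dsn <- orthogonal_design(n, seed = 6)
  y <- 2 - 5e-4 * dsn$depth + rnorm(n, 0, 0.3)
  shuffled <- sample(dsn$depth)
  fit <- partial_regression(y, dsn$lat, dsn$lon, shuffled)
  # permutation oracle: distribution of the slope under 1000 random shuffles
  slopes <- replicate(1000, {
    partial_slope_oracle(y, dsn$lat, dsn$lon, sample(dsn$depth))
  })
  ci <- quantile(slopes, c(0.005, 0.995))
  expect_gt(fit$slope, ci[1])
  expect_lt(fit$slope, ci[2])
})

test_that("degenerate designs are handled as documented", {
  dsn <- orthogonal_design(50, seed = 7)
  y <- 2 - 3e-4 * dsn$depth
  # constant lat and lon: stage 1 collapses to intercept-only, slope = plain OLS
  fit <- suppressWarnings(partial_regression(y, rep(5, 50), rep(20, 50), dsn$depth))
  expect_equal(fit$slope, unname(coef(lm(y ~ dsn$depth))[2]), tolerance = 1e-10)
  expect_error(partial_regression(y, dsn$lat, dsn$lon, rep(1000, 50)), "constant")
  expect_error(partial_regression(y[1:5], dsn$lat[1:5], dsn$lon[1:5], dsn$depth[1:5]),
               "at least 10")
})

test_that("generator-to-trends recovery matches the attenuated closed form", {
  tr <- default_truth(sigma = 0, pred_effect_scale = 0)
  world <- gen_stock_records(tr, small_world(), 800, seed = 23,
                             location_bias = FALSE)
  rec <- world$records
  for (cl in c("meiofauna", "macrofauna", "megafauna")) {
    row <- tr$coefs[tr$coefs$class == cl & tr$coefs$response == "biomass", ]
    r <- rec[rec$size_class == cl, ]
    y <- log10(r$biomass_mgC_m2)
    fit <- partial_regression(y, r$latitude, r$longitude, r$depth_m)
    expect_equal(fit$slope, partial_slope_oracle(y, r$latitude, r$longitude, r$depth_m),
                 tolerance = 1e-9)
    # attenuation of the generative slope is bounded by the design's
    # R^2(depth ~ lat + lon), which is small under uniform sampling
    r2d <- summary(lm(depth_m ~ latitude + longitude, r))$r.squared
    expect_lt(abs(fit$slope - row$b), abs(row$b) * (r2d + 0.02) + 1e-8)
  }
})

test_that("fit_all_classes covers responses and classes, skipping sparse ones", {
  world <- gen_stock_records(default_truth(), small_world(), 120, seed = 29)
  fits <- fit_all_classes(world$records)
  expect_setequal(unique(fits$response), c("biomass", "abundance", "body_size"))
  expect_equal(sum(fits$response == "biomass"), 4)
  expect_true(all(fits$n <= 120))
  # single-class input
  one <- fit_all_classes(world$records[world$records$size_class == "macrofauna", ])
  expect_equal(unique(one$size_class), "macrofauna")
  # empty input: empty output, no crash
  empty <- fit_all_classes(world$records[0, ])
  expect_equal(nrow(empty), 0)
  # sparse class is skipped with a diagnostic
  few <- world$records[world$records$size_class == "megafauna", ][1:5, ]
  sk <- fit_all_classes(few)
  expect_equal(nrow(sk), 0)
  expect_gt(length(attr(sk, "skipped")), 0)
  # equation strings render the sign convention
  expect_match(fits$equation[fits$size_class == "macrofauna" &
                               fits$response == "biomass"], "^Y = .*X$")
})

test_that("latitude parabola recovers a generated polar enhancement", {
  set.seed(41)
  n <- 800
  lat <- runif(n, -80, 80); lon <- runif(n, -179, 179)
  depth <- runif(n, 100, 5500)
  y <- 2.8 - 4e-4 * depth + 2e-4 * lat^2 + rnorm(n, 0, 0.3)
  fit <- latitude_parabola(y, depth, lon, lat)
  expect_true(fit$positive_parabola)
  expect_equal(fit$coef_lat2, 2e-4, tolerance = 0.25)
  expect_gt(fit$r2, 0.05)

  # no latitude effect: the quadratic term is not significant
  y0 <- 2.8 - 4e-4 * depth + rnorm(n, 0, 0.3)
  fit0 <- latitude_parabola(y0, depth, lon, lat)
  expect_false(fit0$positive_parabola && fit0$lat2_p < 1e-4)

  # symmetric data about the equator: linear term vanishes
  lat_s <- c(lat, -lat)
  y_s <- c(y, y)
  fit_s <- latitude_parabola(y_s, c(depth, depth), c(lon, lon), lat_s)
  expect_lt(abs(fit_s$coef_lat * 80), abs(fit_s$coef_lat2 * 80^2) * 0.05 + 1e-6)
  expect_error(latitude_parabola(y, depth, lon, rep(3, n)), "constant")
})
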