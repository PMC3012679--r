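make_records_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

valid_rows <- function() {
  data.frame(
    lat = c(10, -40, 62.1), lon = c(20, -150, 3),
    depth_m = c(50, 3000, 420), size_class = c("macrofauna", "bacteria", "meiofauna"),
    biomass_mgC_m2 = c(120, 250, NA), abundance_per_m2 = c(NA, 1e12, 5e5),
    penetration_cm = c(NA, 10, NA))
}

test_that("read_records validates rows and reports rejections", {
  path <- make_records_csv(valid_rows())
  rec <- read_records(path)
  expect_equal(nrow(rec), 3)
  expect_equal(nrow(attr(rec, "rejected")), 0)

  bad <- rbind(valid_rows(),
               data.frame(lat = 95, lon = 0, depth_m = 100, size_class = "macrofauna",
                          biomass_mgC_m2 = 1, abundance_per_m2 = NA, penetration_cm = NA),
               data.frame(lat = 0, lon = 0, depth_m = 100, size_class = "macrofauna",
                          biomass_mgC_m2 = NA, abundance_per_m2 = NA, penetration_cm = NA),
               data.frame(lat = 0, lon = 0, depth_m = 100, size_class = "meiofauna",
                          biomass_mgC_m2 = 5, abundance_per_m2 = NA, penetration_cm = 10))
  expect_warning(rec <- read_records(make_records_csv(bad)), "rejected")
  expect_equal(nrow(rec), 3)
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rej), 3)
  expect_match(rej$reason[1], "latitude")
  expect_match(rej$reason[2], "neither biomass nor abundance")
  expect_match(rej$reason[3], "non-bacterial")
})

test_that("read_records handles missing columns and empty files", {
  df <- valid_rows(); df$depth_m <- NULL
  expect_error(read_records(make_records_csv(df)), "depth_m")
  empty <- valid_rows()[0, ]
  expect_warning(rec <- read_records(make_records_csv(empty)), "empty")
  expect_equal(nrow(rec), 0)
})

test_that("unit standardization converts to mg C m-2 and is idempotent", {
  df <- valid_rows()
  df$biomass_value <- c(1, NA, 2)        # 1 g wet, -, 2 g dry
  df$biomass_unit <- c("wet g m-2", NA, "dry g m-2")
  df$biomass_mgC_m2 <- c(NA, 250, NA)
  tab <- rbind(default_conversion_table(),
               data.frame(size_class = "macrofauna", unit = "wet g m-2", factor = 50))
  tab <- tab[rev(seq_len(nrow(tab))), ]   # custom factor shadows the default
  out <- standardize_units(df, tab)
  expect_equal(out$biomass_mgC_m2, c(1 * 50, 250, 2 * 400))
  expect_equal(nrow(out), nrow(df))
  # idempotent: a second pass changes nothing
  expect_equal(standardize_units(out, tab), out)
  # unknown pair is a conversion error naming the pair
  df$biomass_unit[1] <- "carats m-2"
  expect_error(standardize_units(df, tab), "macrofauna, carats m-2")
})

test_that("penetration standardization matches the closed form on a noise-free fixture", {
  n <- 40
  set.seed(1)
  pen <- seq(2, 28, length.out = n)
  rec <- data.frame(study_id = "fix", latitude = runif(n, -60, 60),
                    longitude = runif(n, -180, 179), depth_m = 1000,
                    size_class = "bacteria",
                    biomass_mgC_m2 = 10^(2 + 0.05 * pen),
                    abundance_per_m2 = NA_real_, penetration_cm = pen)
  out <- standardize_penetration(rec, reference_cm = 10)
  expect_equal(log10(out$biomass_mgC_m2), rep(2.5, n), tolerance = 1e-8)
  expect_equal(out$study_id, rec$study_id)
  expect_equal(nrow(out), n)
})

test_that("penetration standardization is the identity in degenerate cases", {
  n <- 20
  rec <- data.frame(study_id = "fix", latitude = seq(-50, 50, length.out = n),
                    longitude = seq(-170, 170, length.out = n), depth_m = 500,
                    size_class = "bacteria", biomass_mgC_m2 = rep(100, n),
                    abundance_per_m2 = NA_real_,
                    penetration_cm = rep(10, n))
  # all penetration depths identical: nothing to regress on
  expect_identical(standardize_penetration(rec, 10), rec)
  # zero-slope fixture (stock independent of penetration): exact identity
  rec$penetration_cm <- seq(1, 25, length.out = n)
  out <- standardize_penetration(rec, 10)
  expect_equal(out$biomass_mgC_m2, rec$biomass_mgC_m2, tolerance = 1e-10)
  # non-bacterial records pass through untouched
  mixed <- rbind(rec, within(rec, { size_class <- "macrofauna"; penetration_cm <- NA }))
  out <- standardize_penetration(mixed, 10)
  expect_equal(out[out$size_class == "macrofauna", ],
               mixed[mixed$size_class == "macrofauna", ])
  expect_error(standardize_penetration(rec, reference_cm = 40), "0.5, 29.5")
})

test_that("penetration adjustment is recovered from a generated pen effect", {
  tr <- default_truth(sigma = 0, pred_effect_scale = 0)
  tr$pen_effect <- 0.04
  world <- gen_stock_records(tr, small_world(), 300, seed = 31)
  rec <- world$records
  out <- standardize_penetration(rec, reference_cm = 10)
  b <- out[out$size_class == "bacteria", ]
  raw <- rec[rec$size_class == "bacteria", ]
  # after adjustment the residual penetration dependence is gone
  fit_raw <- lm(log10(raw$biomass_mgC_m2) ~ raw$penetration_cm)
  fit_adj <- lm(log10(b$biomass_mgC_m2) ~ b$penetration_cm)
  expect_gt(abs(coef(fit_raw)[2]), 0.035)
  expect_lt(abs(coef(fit_adj)[2]), 1e-3)
})

test_that("body size is biomass over abundance in ug C", {
  expect_equal(as.numeric(body_size(100, 1000)), 100)
  expect_equal(as.numeric(body_size(0, 1000)), 0)
  b <- runif(20, 1, 1e4); a <- runif(20, 1, 1e7)
  expect_equal(as.numeric(body_size(b, a)) * a / 1000, b)
  out <- body_size(c(100, 50, 2e4), c(1000, 0, 1))
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "n_undefined"), 1L)
  expect_equal(as.logical(attr(out, "extremely_large")), c(FALSE, FALSE, TRUE))
})

test_that("KML export writes one placemark per record and round-trips coordinates", {
  rec <- valid_rows()
  names(rec)[1:2] <- c("latitude", "longitude")
  path <- withr::local_tempfile(fileext = ".kml")
  write_kml(rec[1:2, ], path)
  doc <- xml2::read_xml(path)
  pms <- xml2::xml_find_all(doc, ".//d1:Placemark", xml2::xml_ns(doc))
  expect_length(pms, 2)
  coords <- xml2::xml_text(xml2::xml_find_all(doc, ".//d1:coordinates", xml2::xml_ns(doc)))
  got <- do.call(rbind, lapply(strsplit(coords, ","), function(x) as.numeric(x[1:2])))
  expect_equal(got[, 1], rec$longitude[1:2], tolerance = 1e-6)
  expect_equal(got[, 2], rec$latitude[1:2], tolerance = 1e-6)
  # empty table still yields a valid document
  write_kml(rec[0, ], path)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, ".//d1:Placemark", xml2::xml_ns(doc)), 0)
})
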