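# Synthetic-world generator: bathymetry with shelf/slope/abyss structure,
# 39 mutually correlated environmental predictor grids, a satellite
# coverage-months field that decays poleward, and georeferenced stock records
# drawn from known log-linear generative parameters. Everything is a pure
# function of (parameters, seed) so downstream stages can be validated
# against the generating truth.

## ---- predictor catalogue -------------------------------------------------

productivity_vars <- function() {
  base <- c("chl", "sst", "par", "bbp", "mld", "growth", "carbon", "vgpm", "cbpm")
  c(paste0(base, ".mean"), paste0(base, ".sd"))
}

water_column_vars <- function() {
  c("int.c", "int.n", "det.c", "det.n", "phyt", "zoop", "det.c.flx", "det.n.flx")
}

bottom_water_vars <- function() {
  base <- c("temp", "salin", "oxyg", "nitra", "phos", "si")
  c(paste0(base, ".mean"), paste0(base, ".sd"))
}

#' Names of the 39 environmental predictors
#'
#' Surface-productivity variables (decadal mean and SD of chlorophyll, SST,
#' irradiance, backscatter, mixed-layer depth, growth rate, phytoplankton
#' carbon, and two net-primary-production models), water-column standing and
#' flux terms, bottom-water properties (annual mean and seasonal SD), and
#' water depth.
#'
#' @return Character vector of length 39.
#' @export
predictor_names <- function() {
  c(productivity_vars(), water_column_vars(), bottom_water_vars(), "depth")
}

# extraction box size per predictor: 3x3 for the satellite-derived
# productivity fields (except mixed-layer depth), 1x1 for everything else
predictor_box_sizes <- function() {
  box <- setNames(rep(1L, 39), predictor_names())
  three <- c("chl", "sst", "par", "bbp", "growth", "carbon", "vgpm", "cbpm")
  box[paste0(rep(three, each = 2), c(".mean", ".sd"))] <- 3L
  box
}

## ---- random-field helpers ------------------------------------------------

# separable Gaussian smoothing; longitude wraps, latitude clamps at the poles
smooth_field <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  n_lat <- nrow(m); n_lon <- ncol(m)
  out <- matrix(0, n_lat, n_lon)
  for (o in -r:r)
    out <- out + k[o + r + 1] * m[, (seq_len(n_lon) - 1 + o) %% n_lon + 1]
  m2 <- out
  out <- matrix(0, n_lat, n_lon)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n_lat) + o, 1L), n_lat)
    out <- out + k[o + r + 1] * m2[idx, , drop = FALSE]
  }
  out
}

# unit-variance Gaussian random field with ~sigma-cell correlation length
gaussian_field <- function(n_lat, n_lon, sigma) {
  f <- smooth_field(matrix(rnorm(n_lat * n_lon), n_lat, n_lon), sigma)
  (f - mean(f)) / sd(as.vector(f))
}

# 8-neighbour binary dilation with longitude wrap
dilate8 <- function(m) {
  n_lat <- nrow(m); n_lon <- ncol(m)
  shl <- function(x, o) x[, (seq_len(n_lon) - 1 + o) %% n_lon + 1, drop = FALSE]
  out <- m
  for (o in c(-1L, 0L, 1L)) {
    s <- shl(m, o)
    out <- out | s
    out <- out | rbind(s[-1, , drop = FALSE], FALSE)          # from the north
    out <- out | rbind(FALSE, s[-n_lat, , drop = FALSE])      # from the south
  }
  out
}

# grid-steps to the nearest land cell (0 on land)
dist_to_land <- function(land) {
  d <- matrix(NA_real_, nrow(land), ncol(land))
  d[land] <- 0
  frontier <- land
  k <- 0
  while (anyNA(d)) {
    k <- k + 1
    if (!any(frontier)) { d[is.na(d)] <- k; break }   # no land at all
    frontier <- dilate8(frontier)
    newly <- frontier & is.na(d)
    d[newly] <- k
  }
  d
}

## ---- bathymetry ----------------------------------------------------------

#' Generate synthetic global bathymetry
#'
#' Builds a land mask from a smooth random field (contiguous continents),
#' then assigns ocean depth as an increasing function of distance to land so
#' that shelves (< 200 m) hug the coasts, slopes connect them to the deep
#' sea, and abyssal plains (> 3000 m) fill the remainder. Depth-band
#' boundaries are placed on area-weighted (cosine-latitude) quantiles of the
#' distance field, so the abyssal fraction of ocean *area* matches
#' `abyssal_frac` by construction.
#'
#' @param seed integer seed; the grid is a pure function of the arguments.
#' @param n_lat,n_lon lattice size (default 180 x 360, i.e. 1 degree).
#' @param abyssal_frac target fraction of ocean area deeper than 3000 m
#'   (default 0.75, the approximate hypsography of the real ocean).
#' @param shelf_frac target fraction of ocean area shallower than 200 m
#'   (default 0.06).
#' @param land_frac fraction of grid cells that are land (default 0.29).
#' @param max_depth deepest abyssal depth in m (default 6000).
#' @param constant_depth if given, every ocean cell gets exactly this depth
#'   (degenerate configuration used in tests).
#' @return A `world_grid` named `"depth"`, meters positive downward, NA on
#'   land.
#' @export
gen_bathymetry <- function(seed, n_lat = 180, n_lon = 360, abyssal_frac = 0.75,
                           shelf_frac = 0.06, land_frac = 0.29,
                           max_depth = 6000, constant_depth = NULL) {
  if (n_lat < 4 || n_lon < 4) stopf("grid dimensions must be at least 4 x 4")
  if (abyssal_frac + shelf_frac >= 1) stopf("shelf_frac + abyssal_frac must be < 1")
  vals <- with_seed(seed, {
    sigma <- max(2, round(n_lat / 18))          # ~10 degree continents
    f <- gaussian_field(n_lat, n_lon, sigma)
    land <- f > quantile(f, 1 - land_frac)
    v <- matrix(NA_real_, n_lat, n_lon)
    ocean <- !land
    if (!is.null(constant_depth)) {
      if (constant_depth <= 0) stopf("constant_depth must be positive")
      v[ocean] <- constant_depth
    } else {
      d <- dist_to_land(land)
      lat <- grid_centers(n_lat, -90, 90)
      w <- matrix(cos(lat * pi / 180), n_lat, n_lon)
      oc <- which(ocean)
      key <- d[oc] + runif(length(oc))          # jitter breaks rank ties
      ord <- order(key)
      r <- cumsum(w[oc][ord]) / sum(w[oc])      # area-weighted rank in (0, 1]
      depth <- numeric(length(oc))
      band <- function(r, r0, r1, d0, d1) d0 + (r - r0) / (r1 - r0) * (d1 - d0)
      shelf <- r <= shelf_frac
      slope <- r > shelf_frac & r <= 1 - abyssal_frac
      abyss <- r > 1 - abyssal_frac
      depth[shelf] <- band(r[shelf], 0, shelf_frac, 10, 199.9)
      depth[slope] <- band(r[slope], shelf_frac, 1 - abyssal_frac, 200, 2999.9)
      depth[abyss] <- band(r[abyss], 1 - abyssal_frac, 1, 3000.1, max_depth)
      v[oc[ord]] <- depth
    }
    v
  })
  world_grid(vals, name = "depth", units = "m")
}

## ---- predictor grids and coverage ---------------------------------------

#' Generate the 39 predictor grids and the coverage-months field
#'
#' Productivity variables share a latitudinal forcing (warm, bright, and
#' productive at low latitudes) plus a common spatially correlated anomaly
#' field, so their pairwise correlations are high by construction; each adds
#' its own short-range Gaussian-field noise. Water-column stocks and fluxes
#' decay with water depth; bottom-water properties are smooth functions of
#' depth and latitude with small anomalies. The coverage grid holds months of
#' satellite measurements (0-120): full coverage equatorward of 50 degrees,
#' declining monotonically toward the poles (winter darkness and cloud
#' cover).
#'
#' @param seed integer seed.
#' @param bathymetry a `world_grid` from [gen_bathymetry()].
#' @param shared_weight weight of the shared (forcing + common anomaly)
#'   component in each productivity variable (default 0.8; guarantees
#'   pairwise correlations well above 0.5).
#' @return Object of class `synthetic_world`: list with `bathymetry`,
#'   `grids` (named list of 39 `world_grid`s including `depth`), `coverage`
#'   (integer months `world_grid`), and empty `records`/`truth` slots.
#' @export
gen_predictor_grids <- function(seed, bathymetry, shared_weight = 0.8) {
  if (missing(bathymetry) || !inherits(bathymetry, "world_grid"))
    stopf("bathymetry must be a world_grid (see gen_bathymetry)")
  n_lat <- nrow(bathymetry$values); n_lon <- ncol(bathymetry$values)
  depth <- bathymetry$values
  ocean <- !is.na(depth)
  latm <- matrix(grid_centers(n_lat, -90, 90), n_lat, n_lon)
  sig <- max(2, round(n_lat / 60))              # ~3 degree anomaly scale
  w <- shared_weight

  grids <- with_seed(seed, {
    coslat <- cos(latm * pi / 180)
    forcing <- coslat + 0.3 * exp(-(latm / 12)^2)   # equatorial enhancement
    shared <- forcing + 0.35 * gaussian_field(n_lat, n_lon, sig)
    shared <- (shared - mean(shared)) / sd(as.vector(shared))

    mk <- function(level, scale, field, name, units) {
      v <- level + scale * field
      v[!ocean] <- NA_real_
      world_grid(v, name = name, units = units)
    }
    prod_field <- function() w * shared + (1 - w) * gaussian_field(n_lat, n_lon, sig)

    g <- list()
    spec <- list(  # level, scale, units for the productivity means
      chl = c(0.4, 0.35, "mg m-3"), sst = c(14, 9, "degC"),
      par = c(35, 12, "Einstein m-2 day-1"), bbp = c(0.002, 0.001, "m-1"),
      mld = c(40, 15, "m"), growth = c(0.5, 0.25, "divisions day-1"),
      carbon = c(25, 12, "mg m-3"), vgpm = c(500, 250, "mg C m-2 day-1"),
      cbpm = c(450, 220, "mg C m-2 day-1")
    )
    for (v in names(spec)) {
      s <- spec[[v]]
      lev <- as.numeric(s[1]); sc <- as.numeric(s[2])
      f_mean <- prod_field()
      g[[paste0(v, ".mean")]] <- mk(lev, sc, f_mean, paste0(v, ".mean"), s[3])
      # seasonal SD tracks the mean level (mean and SD rank similarly)
      f_sd <- 0.85 * f_mean + 0.15 * gaussian_field(n_lat, n_lon, sig)
      g[[paste0(v, ".sd")]] <- mk(0.3 * lev, 0.3 * sc, f_sd, paste0(v, ".sd"), s[3])
    }

    # water-column integrals and export fluxes: productivity signal
    # attenuated with water depth (food supply fading toward the abyss)
    atten <- exp(-ifelse(is.na(depth), 0, depth) / 1500)
    wc <- list(int.c = 4000, int.n = 600, det.c = 1500, det.n = 220,
               phyt = 120, zoop = 60, det.c.flx = 60, det.n.flx = 9)
    for (v in names(wc)) {
      lev <- wc[[v]]
      f <- (0.6 * shared + 0.4 * gaussian_field(n_lat, n_lon, sig)) * atten
      g[[v]] <- mk(lev, 0.45 * lev, f, v, "mg m-2")
    }

    # bottom-water properties: smooth in depth and latitude, small anomalies
    dd <- ifelse(is.na(depth), 0, depth)
    bw_mean <- list(
      temp  = 1.5 + 24 * coslat^2 * exp(-dd / 700),
      salin = 34.7 + 0.4 * coslat - 0.1 * exp(-dd / 1000),
      oxyg  = 6.5 - 2.5 * exp(-dd / 900) * coslat,
      nitra = 15 + 18 * (1 - exp(-dd / 1200)),
      phos  = 1 + 1.4 * (1 - exp(-dd / 1200)),
      si    = 30 + 90 * (1 - exp(-dd / 1500))
    )
    bw_noise <- c(temp = 0.5, salin = 0.1, oxyg = 0.4, nitra = 1.5,
                  phos = 0.12, si = 8)
    bw_units <- c(temp = "degC", salin = "ppm", oxyg = "ml l-1",
                  nitra = "umol l-1", phos = "umol l-1", si = "umol l-1")
    for (v in names(bw_mean)) {
      f <- gaussian_field(n_lat, n_lon, sig)
      g[[paste0(v, ".mean")]] <- mk(bw_mean[[v]], bw_noise[[v]], f,
                                    paste0(v, ".mean"), bw_units[[v]])
      f2 <- 0.7 * f + 0.3 * gaussian_field(n_lat, n_lon, sig)
      g[[paste0(v, ".sd")]] <- mk(0.25 * bw_noise[[v]] * 2, 0.2 * bw_noise[[v]],
                                  f2, paste0(v, ".sd"), bw_units[[v]])
    }

    g[["depth"]] <- bathymetry
    g[predictor_names()]
  })

  # months of satellite coverage: 120 equatorward of 50 deg, then a strict
  # linear decline to near zero at the poles
  lat <- grid_centers(n_lat, -90, 90)
  cov_lat <- ifelse(abs(lat) <= 50, 120, pmax(0, round(120 - (abs(lat) - 50) * 2.9)))
  covm <- matrix(cov_lat, n_lat, n_lon)
  covm[!ocean] <- NA_real_
  coverage <- world_grid(covm, name = "coverage", units = "months")

  structure(list(bathymetry = bathymetry, grids = grids, coverage = coverage,
                 records = NULL, truth = NULL),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d x %d lattice, %d predictor grids, %s records\n",
              nrow(x$bathymetry$values), ncol(x$bathymetry$values),
              length(x$grids),
              if (is.null(x$records)) "no" else nrow(x$records)))
  invisible(x)
}

## ---- generative truth ----------------------------------------------------

#' Generative parameters for synthetic stock records
#'
#' One row per (size class, response): intercept `a` (log10 mg C m-2 for
#' biomass, log10 individuals m-2 for abundance), depth slope `b` (per m,
#' negative: stocks decline with depth), linear latitude/longitude
#' coefficients, an optional quadratic latitude coefficient (polar
#' enhancement), and the residual SD `sigma` (log10 units). `pred_effects`
#' gives, per class, weights applied to z-scored predictor grids so that
#' food-supply covariates carry real signal for the forest to find.
#'
#' @param coefs data.frame with columns `class`, `response`, `a`, `b`,
#'   `c_lat`, `c_lon`, `c_lat2`, `sigma`.
#' @param pred_effects named list (by class) of named weight vectors over
#'   grid names.
#' @param pen_effect slope of bacterial log10 stock on sediment penetration
#'   depth (cm; default 0).
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(coefs, pred_effects = list(), pen_effect = 0) {
  need <- c("class", "response", "a", "b", "c_lat", "c_lon", "c_lat2", "sigma")
  miss <- setdiff(need, names(coefs))
  if (length(miss)) stopf("coefs is missing columns: %s", paste(miss, collapse = ", "))
  if (any(coefs$sigma < 0)) stopf("residual sigma must be >= 0")
  if (any(!is.finite(coefs$b))) stopf("depth slopes must be finite")
  structure(list(coefs = coefs, pred_effects = pred_effects,
                 pen_effect = pen_effect),
            class = "truth_params")
}

#' Default generative truth for the four major size classes
#'
#' Depth intercepts and slopes are the field's canonical global depth-decline
#' coefficients for log10 biomass (mg C m-2) and log10 abundance
#' (individuals m-2): bacterial stocks essentially depth-independent, the
#' three metazoan classes declining log-linearly. Latitude/longitude trends
#' are mild and linear (a quadratic latitude term is available through the
#' `c_lat2` column for polar-enhancement experiments). Predictor-effect
#' weights put
#' food-supply signal on surface-productivity covariates. The residual SD
#' defaults to 0.35 log10 units, except macrofauna biomass at 0.5 — the
#' largest and most heterogeneous dataset, with the least stable model
#' performance.
#'
#' @param sigma residual SD in log10 units; a scalar applies to every
#'   (class, response). The default `NULL` uses the canonical values above.
#' @param pred_effect_scale multiplier on the default predictor-effect
#'   weights (set 0 to generate from the pure depth/latitude model).
#' @return A `truth_params` object.
#' @export
default_truth <- function(sigma = NULL, pred_effect_scale = 1) {
  cls <- major_classes()
  coefs <- rbind(
    data.frame(class = cls, response = "biomass",
               a = c(2.4, 2.18, 3.05, 1.81),
               b = c(-1.22e-06, -2.39e-04, -5.15e-04, -3.07e-04)),
    data.frame(class = cls, response = "abundance",
               a = c(13.27, 5.73, 3.5, -0.68),
               b = c(-3.58e-05, -1.25e-04, -1.95e-04, -2.82e-04))
  )
  coefs$c_lat <- 0.002
  coefs$c_lon <- 0.0005
  coefs$c_lat2 <- 0
  coefs$sigma <- if (is.null(sigma)) {
    ifelse(coefs$class == "macrofauna" & coefs$response == "biomass", 0.5, 0.35)
  } else sigma
  s <- pred_effect_scale
  pred_effects <- lapply(list(
    bacteria   = c(vgpm.mean = 0.25, cbpm.mean = 0.2, sst.mean = 0.2,
                   mld.mean = 0.15, par.mean = 0.15),
    meiofauna  = c(vgpm.mean = 0.3, chl.mean = 0.2, carbon.mean = 0.2),
    macrofauna = c(cbpm.mean = 0.3, sst.mean = 0.2, bbp.mean = 0.2),
    megafauna  = c(vgpm.mean = 0.25, chl.mean = 0.2, growth.mean = 0.15)
  ), function(wts) wts * s)
  truth_params(coefs, pred_effects)
}

## ---- stock records -------------------------------------------------------

#' Generate synthetic stock records from a known truth
#'
#' For each class, sampling cells are drawn from the ocean with a bias toward
#' shelves and the northern hemisphere (emulating the real database's survey
#' coverage; disable with `location_bias = FALSE`). Each record's log10 stock
#' is `a + b * depth + c_lat * lat + c_lat2 * lat^2 + c_lon * lon +
#' f(predictors) + eps`, `eps ~ N(0, sigma)`, where `f` applies the class's
#' predictor-effect weights to z-scored grid values at the record's cell.
#' Bacterial records additionally carry a sediment penetration depth in
#' [0.5, 29.5] cm with at least ~90% of draws in the 5-15 cm band.
#'
#' @param truth a `truth_params` object (see [default_truth()]).
#' @param world a `synthetic_world` from [gen_predictor_grids()].
#' @param n_per_class records per size class (>= 10).
#' @param seed integer seed.
#' @param location_bias bias sampling toward shelves / northern hemisphere.
#' @param depth_jitter relative jitter of record depth around the cell depth
#'   (default 0.03).
#' @return The `synthetic_world` with a `records` data.frame (columns
#'   `study_id`, `latitude`, `longitude`, `depth_m`, `size_class`,
#'   `biomass_mgC_m2`, `abundance_per_m2`, `penetration_cm`) and the truth
#'   attached.
#' @export
gen_stock_records <- function(truth, world, n_per_class = 600, seed = 1,
                              location_bias = TRUE, depth_jitter = 0.03) {
  stopifnot(inherits(truth, "truth_params"), inherits(world, "synthetic_world"))
  if (n_per_class < 10) stopf("n_per_class must be at least 10")
  if (any(truth$coefs$sigma < 0)) stopf("residual sigma must be >= 0")
  depth <- world$bathymetry$values
  oc <- which(!is.na(depth))
  n_lat <- nrow(depth); n_lon <- ncol(depth)
  lat <- grid_centers(n_lat, -90, 90)
  lon <- grid_centers(n_lon, -180, 180)
  dlat <- 180 / n_lat; dlon <- 360 / n_lon
  cell_lat <- lat[(oc - 1) %% n_lat + 1]
  cell_depth <- depth[oc]
  wt <- if (location_bias) {
    w <- ifelse(cell_depth < 200, 3, ifelse(cell_depth < 3000, 2, 1))
    w * ifelse(cell_lat > 0, 2, 1) * cos(cell_lat * pi / 180)
  } else cos(cell_lat * pi / 180)

  # z-score predictor grids once (over ocean cells)
  zgrids <- lapply(world$grids, function(g) {
    v <- g$values
    mu <- mean(v, na.rm = TRUE); s <- sd(as.vector(v), na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (v - mu) / s
  })

  classes <- unique(truth$coefs$class)
  records <- with_seed(seed, {
    out <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      pick <- sample(seq_along(oc), n_per_class, replace = TRUE, prob = wt)
      cells <- oc[pick]
      i <- (cells - 1) %% n_lat + 1
      j <- (cells - 1) %/% n_lat + 1
      rec_lat <- lat[i] + runif(n_per_class, -dlat / 2, dlat / 2) * 0.98
      rec_lon <- lon[j] + runif(n_per_class, -dlon / 2, dlon / 2) * 0.98
      rec_depth <- pmax(1, depth[cells] * (1 + runif(n_per_class, -depth_jitter, depth_jitter)))
      f <- numeric(n_per_class)
      wts <- truth$pred_effects[[cl]]
      if (length(wts)) {
        bad <- setdiff(names(wts), names(zgrids))
        if (length(bad)) stopf("unknown predictor(s) in effects: %s", paste(bad, collapse = ", "))
        for (v in names(wts)) f <- f + wts[[v]] * zgrids[[v]][cells]
      }
      pen <- rep(NA_real_, n_per_class)
      if (cl == "bacteria") {
        inband <- runif(n_per_class) < 0.9
        pen <- ifelse(inband, runif(n_per_class, 5, 15),
                      ifelse(runif(n_per_class) < 0.5,
                             runif(n_per_class, 0.5, 5), runif(n_per_class, 15, 29.5)))
      }
      rec <- data.frame(study_id = sprintf("synthetic-%s", cl),
                        latitude = rec_lat, longitude = rec_lon,
                        depth_m = rec_depth, size_class = cl,
                        biomass_mgC_m2 = NA_real_, abundance_per_m2 = NA_real_,
                        penetration_cm = pen, stringsAsFactors = FALSE)
      for (resp in c("biomass", "abundance")) {
        row <- truth$coefs[truth$coefs$class == cl & truth$coefs$response == resp, ]
        if (nrow(row) == 0) next
        lg <- row$a + row$b * rec_depth + row$c_lat * rec_lat +
          row$c_lat2 * rec_lat^2 + row$c_lon * rec_lon + f +
          rnorm(n_per_class, 0, row$sigma)
        if (cl == "bacteria" && truth$pen_effect != 0)
          lg <- lg + truth$pen_effect * (pen - 10)
        if (resp == "biomass") rec$biomass_mgC_m2 <- 10^lg
        else rec$abundance_per_m2 <- 10^lg
      }
      out[[ci]] <- rec
    }
    do.call(rbind, out)
  })
  rownames(records) <- NULL
  world$records <- records
  world$truth <- truth
  world
}

#' Write a synthetic world to disk
#'
#' Records as CSV, each grid and the coverage field as long-format CSV, and a
#' `manifest.json` recording the lattice, seed/parameter provenance passed in
#' `params`, and the generative truth table.
#'
#' @param world a `synthetic_world` with records attached.
#' @param dir output directory (created if needed).
#' @param params optional named list recorded verbatim in the manifest.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, params = list()) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(world$records))
    write.csv(world$records, file.path(dir, "records.csv"), row.names = FALSE)
  gdir <- file.path(dir, "grids")
  dir.create(gdir, showWarnings = FALSE)
  for (nm in names(world$grids))
    write_grid_csv(world$grids[[nm]], file.path(gdir, paste0(nm, ".csv")))
  write_grid_csv(world$coverage, file.path(dir, "coverage.csv"))
  manifest <- list(
    n_lat = nrow(world$bathymetry$values), n_lon = ncol(world$bathymetry$values),
    predictors = names(world$grids), params = params,
    truth = if (!is.null(world$truth)) world$truth$coefs else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
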