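# Global prediction: per-cell forest predictions for each scenario, mean and
# coefficient of variation, size-class combination in linear space, IDW
# refinement, Jenks classification, area-weighted global and zonal
# integrals, and living-carbon residence time.

#' Predict a global grid from a scenario ensemble
#'
#' Every ocean cell with a complete 1-degree predictor vector is predicted by
#' each scenario's forest (in log10 response space). The cell mean, SD, and
#' coefficient of variation (SD/mean * 100%) across scenarios measure the
#' prediction and its stability; predictions stay in log10 space until
#' size classes are combined.
#'
#' @param ensemble a `scenario_ensemble`.
#' @param world the `synthetic_world` with the predictor grids.
#' @param cv_space compute mean/SD/CV on the log10 predictions (default,
#'   matching how the scenario outputs are aggregated) or after
#'   back-transforming to linear space.
#' @return Object of class `prediction_grid`: `mean`, `sd`, `cv` matrices
#'   (log10 response units), the per-scenario array, `depth`, cell-center
#'   coordinates, and counts of unpredictable cells.
#' @export
grid_predict <- function(ensemble, world, cv_space = c("log10", "linear")) {
  cv_space <- match.arg(cv_space)
  stopifnot(inherits(ensemble, "scenario_ensemble"))
  grids <- world$grids[ensemble$predictors]
  n_lat <- nrow(world$bathymetry$values); n_lon <- ncol(world$bathymetry$values)
  X <- vapply(grids, function(g) as.vector(g$values), numeric(n_lat * n_lon))
  ocean <- !is.na(world$bathymetry$values)
  usable <- ocean & matrix(complete.cases(X), n_lat, n_lon)
  n_bad <- sum(ocean & !usable)
  if (!any(usable)) {
    warnf("no cell has a complete predictor vector; the map is all NA")
  } else if (n_bad > 0) {
    warnf("%d ocean cell(s) lack complete predictors and stay NA", n_bad)
  }
  idx <- which(as.vector(usable))
  k <- length(ensemble$scenarios)
  preds <- array(NA_real_, dim = c(n_lat, n_lon, k))
  for (s in seq_len(k)) {
    layer <- matrix(NA_real_, n_lat, n_lon)
    if (length(idx))
      layer[idx] <- predict(ensemble$scenarios[[s]]$model, X[idx, , drop = FALSE])
    preds[, , s] <- layer
  }
  agg <- if (cv_space == "linear") 10^preds else preds
  m <- rowMeans(agg, dims = 2)
  sdv <- if (k > 1) sqrt(pmax(rowSums(agg^2, dims = 2) - k * m^2, 0) / (k - 1))
         else m * 0
  cv <- sdv / m * 100
  if (cv_space == "linear") m <- log10(m)   # keep log10 convention for `mean`
  structure(list(
    class = ensemble$class, response = ensemble$response,
    lat = grid_centers(n_lat, -90, 90), lon = grid_centers(n_lon, -180, 180),
    scenario_log10 = preds, mean = m, sd = sdv, cv = cv,
    depth = world$bathymetry$values, cv_space = cv_space,
    n_unpredicted = n_bad
  ), class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("prediction_grid: %s %s, %d x %d, %d predicted cells, mean log10 %.2f\n",
              x$class, x$response, length(x$lat), length(x$lon),
              sum(!is.na(x$mean)), mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

# back-transformed (linear-scale) world_grid from a prediction grid
prediction_linear <- function(pg, bias_correction = FALSE) {
  v <- 10^pg$mean
  if (bias_correction) {
    # lognormal mean correction using the cross-scenario SD as spread proxy
    v <- 10^(pg$mean + (log(10) / 2) * pg$sd^2)
  }
  world_grid(v, name = paste0(pg$class, "_", pg$response), units = "mg C m-2")
}

#' Combine size-class predictions into a total biomass grid
#'
#' Per cell, the class predictions are back-transformed from log10 and
#' summed in linear space (mg C m-2). By default a cell where any class is
#' NA yields NA (`strict`); with `strict = FALSE` the partial sum over
#' available classes is used.
#'
#' @param grids list of `prediction_grid`s (one per size class) or linear
#'   `world_grid`s on the same lattice.
#' @param strict NA propagation policy (default TRUE).
#' @param bias_correction apply a lognormal back-transform correction using
#'   the cross-scenario SD (default FALSE: plain `10^x`).
#' @return A linear-scale `world_grid` of total biomass (mg C m-2).
#' @export
combine_classes <- function(grids, strict = TRUE, bias_correction = FALSE) {
  lin <- lapply(grids, function(g) {
    if (inherits(g, "prediction_grid")) prediction_linear(g, bias_correction)
    else g
  })
  dims <- lapply(lin, function(g) dim(g$values))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stopf("class grids are on different lattices")
  acc <- matrix(0, nrow(lin[[1]]$values), ncol(lin[[1]]$values))
  nas <- matrix(FALSE, nrow(acc), ncol(acc))
  anyv <- matrix(FALSE, nrow(acc), ncol(acc))
  for (g in lin) {
    v <- g$values
    nas <- nas | is.na(v)
    anyv <- anyv | !is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  if (strict) acc[nas] <- NA_real_ else acc[!anyv] <- NA_real_
  world_grid(acc, name = "total_biomass", units = "mg C m-2")
}

#' Inverse-distance-weighted refinement of a coarse grid
#'
#' Interpolates a 1-degree grid to a finer lattice (default 0.1 degree) for
#' smooth display. Each fine cell is the d^-power weighted mean of the
#' `n_neighbors` nearest coarse ocean cell centers (planar degrees,
#' longitude wrapped across the dateline); a fine cell whose center
#' coincides with a coarse center takes that cell's value exactly, and fine
#' cells over coarse land stay NA.
#'
#' @param grid a `world_grid` (or `prediction_grid`, whose log10 mean is
#'   used).
#' @param factor refinement factor (default 10: 1 degree to 0.1 degree).
#' @param power IDW exponent (> 0, default 2).
#' @param n_neighbors coarse neighbors used (>= 1, default 12).
#' @param max_radius search radius in coarse cells (default 15); fine cells
#'   with no ocean neighbor within it stay NA.
#' @param mask_land keep the coarse land mask (default TRUE); with FALSE
#'   every fine cell within reach of ocean data is interpolated.
#' @return A `world_grid` on the refined lattice.
#' @export
idw_interpolate <- function(grid, factor = 10, power = 2, n_neighbors = 12,
                            max_radius = 15, mask_land = TRUE) {
  if (inherits(grid, "prediction_grid"))
    grid <- world_grid(grid$mean, name = paste0(grid$class, "_log10"), units = "log10")
  if (power <= 0) stopf("power must be > 0")
  if (n_neighbors < 1) stopf("n_neighbors must be >= 1")
  fine <- idw_refine_cpp(grid$values, grid$lat, grid$lon, as.integer(factor),
                         power, as.integer(n_neighbors), as.integer(max_radius),
                         isTRUE(mask_land))
  world_grid(fine, name = grid$name, units = grid$units)
}

#' Jenks natural-breaks classification
#'
#' Fisher-Jenks optimal 1-D classification: chooses `k - 1` cut points
#' minimizing the total within-class sum of squared deviations (exact
#' dynamic program, deterministic). Used to classify map values for display.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes (>= 2, <= number of distinct values).
#' @return Numeric vector of length `k`: the upper bound of each class (the
#'   last value falling in it); the final element is `max(values)`.
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(values[!is.na(values)])
  if (k < 2) stopf("k must be at least 2")
  if (length(unique(x)) < k)
    stopf("k = %d exceeds the %d distinct values", k, length(unique(x)))
  ends <- jenks_dp_cpp(x, as.integer(k))
  x[ends]
}

# per-cell area in km^2 under the equidistant cylindrical approximation
cell_area_km2 <- function(lat, a0 = 12343) a0 * cos(lat * pi / 180)

#' Area-weighted global integral of a biomass grid
#'
#' `Global integral = sum over ocean cells of cell value (mg C m-2) x
#' equatorial cell area (A0, ~12343 km^2 for a 1-degree cell) x
#' cos(latitude)`, converted to megatons of carbon (1 Mt = 1e15 mg).
#'
#' @param grid linear-scale `world_grid` in mg C m-2 (land NA).
#' @param a0 equatorial cell area in km^2 (default 12343).
#' @return Megatons C (numeric scalar). Errors on negative cell values.
#' @export
global_integral <- function(grid, a0 = 12343) {
  v <- grid$values
  if (any(v < 0, na.rm = TRUE)) stopf("biomass grid has negative values")
  area <- matrix(cell_area_km2(grid$lat, a0), nrow(v), ncol(v))
  sum(v * area, na.rm = TRUE) * 1e6 / 1e15   # mg m-2 * km2 -> Mt
}

# total ocean area of a grid, km^2
ocean_area_km2 <- function(grid, a0 = 12343) {
  v <- grid$values
  area <- matrix(cell_area_km2(grid$lat, a0), nrow(v), ncol(v))
  sum(area[!is.na(v)])
}

#' Zonal integrals of a biomass grid
#'
#' Assigns ocean cells to 100-m depth bins (half-open, lower-inclusive;
#' cells deeper than the last edge fall into a final open-ended bin) or
#' 2-degree latitude bins, and integrates biomass per bin with the same
#' cos(latitude) area weighting as [global_integral()], alongside the
#' seafloor area per bin. Bin masses sum exactly to the global integral.
#'
#' @param grid linear-scale `world_grid` (mg C m-2).
#' @param bathymetry depth `world_grid` on the same lattice (needed for
#'   depth binning).
#' @param mode `"depth_100m"` or `"lat_2deg"`.
#' @param a0 equatorial cell area, km^2.
#' @return data.frame `bin_lo`, `bin_hi`, `mass_Mt`, `area_km2`.
#' @export
zonal_integrals <- function(grid, bathymetry, mode = c("depth_100m", "lat_2deg"),
                            a0 = 12343) {
  mode <- match.arg(mode)
  v <- grid$values
  if (!identical(dim(v), dim(bathymetry$values)))
    stopf("grid and bathymetry are on different lattices")
  area <- matrix(cell_area_km2(grid$lat, a0), nrow(v), ncol(v))
  oc <- which(!is.na(v))
  mass <- v[oc] * area[oc] * 1e6 / 1e15
  if (mode == "depth_100m") {
    d <- bathymetry$values[oc]
    max_edge <- max(100, 100 * ceiling(max(d, na.rm = TRUE) / 100))
    bin <- pmin(floor(d / 100), max_edge / 100 - 1)
    lo <- sort(unique(bin)) * 100
    hi <- lo + 100
    key <- bin * 100
  } else {
    latc <- matrix(grid$lat, nrow(v), ncol(v))[oc]
    bin <- floor((latc + 90) / 2)
    lo <- sort(unique(bin)) * 2 - 90
    hi <- lo + 2
    key <- bin * 2 - 90
  }
  mass_by <- vapply(lo, function(b) sum(mass[key == b]), numeric(1))
  area_by <- vapply(lo, function(b) sum(area[oc][key == b]), numeric(1))
  data.frame(bin_lo = lo, bin_hi = hi, mass_Mt = mass_by, area_km2 = area_by)
}

#' Residence time of seafloor living carbon
#'
#' Standing mass divided by net throughput: `mass / (poc_flux - burial)`.
#' With the global living-carbon stock in megatons and fluxes in megatons
#' per day the result is in days.
#'
#' @param total_mass_Mt standing stock, megaton C.
#' @param poc_flux_Mt_day particulate organic carbon flux to the seafloor,
#'   megaton C per day.
#' @param burial_Mt_day carbon burial, megaton C per day (default 0).
#' @return Days (numeric scalar).
#' @export
residence_time <- function(total_mass_Mt, poc_flux_Mt_day, burial_Mt_day = 0) {
  if (burial_Mt_day < 0) stopf("burial must be >= 0")
  if (poc_flux_Mt_day <= burial_Mt_day)
    stopf("net flux must be positive (flux %.3g <= burial %.3g)",
          poc_flux_Mt_day, burial_Mt_day)
  total_mass_Mt / (poc_flux_Mt_day - burial_Mt_day)
}

#' Write per-class prediction grids as a long-format CSV
#'
#' One row per ocean cell: `latitude`, `longitude`, `depth`, then one log10
#' biomass (or abundance) column per size class — the layout of a global
#' 1-degree prediction table.
#'
#' @param grids named list of `prediction_grid`s (names = size classes).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(grids, path) {
  g1 <- grids[[1]]
  keep <- which(!is.na(g1$depth), arr.ind = TRUE)
  df <- data.frame(latitude = g1$lat[keep[, 1]], longitude = g1$lon[keep[, 2]],
                   depth = g1$depth[keep])
  for (nm in names(grids)) df[[nm]] <- grids[[nm]]$mean[keep]
  df <- df[order(df$latitude, df$longitude), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format prediction CSV
#'
#' Inverse of [write_prediction_csv()]: rebuilds one log10 `world_grid` per
#' class column plus the depth grid. Accepts any table with `latitude`,
#' `longitude`, `depth` and one column per size class in log10 scale.
#'
#' @param path CSV file.
#' @param n_lat,n_lon lattice dimensions (default 1-degree global).
#' @return List: `classes` (named list of log10 `world_grid`s), `depth`
#'   (`world_grid`).
#' @export
read_prediction_csv <- function(path, n_lat = 180, n_lon = 360) {
  df <- read.csv(path)
  need <- c("latitude", "longitude", "depth")
  if (!all(need %in% names(df)))
    stopf("prediction CSV must have columns %s", paste(need, collapse = ", "))
  cls <- setdiff(names(df), need)
  proto <- world_grid(matrix(NA_real_, n_lat, n_lon))
  ij <- grid_cell_index(proto, df$latitude, df$longitude)
  depth <- proto
  depth$values[ij] <- df$depth
  depth$name <- "depth"; depth$units <- "m"
  classes <- lapply(cls, function(nm) {
    g <- proto
    g$values[ij] <- df[[nm]]
    g$name <- nm; g$units <- "log10 mg C m-2"
    g
  })
  names(classes) <- cls
  list(classes = classes, depth = depth)
}

#' Global biomass summary from per-class linear grids
#'
#' Computes the global integral per class and in total, the class shares,
#' the continental-shelf (<= 200 m) biomass and area shares, the share of
#' biomass deeper than 3000 m, and the shares poleward of 60 degrees and
#' equatorward of 23.5 degrees, plus the residence time for a given
#' POC-flux/burial budget.
#'
#' @param class_grids named list of linear-scale `world_grid`s (mg C m-2),
#'   one per size class.
#' @param bathymetry depth `world_grid` on the same lattice.
#' @param poc_flux_Mt_day,burial_Mt_day carbon budget for the residence
#'   time (defaults 3.835 and 0.82 Mt C/day).
#' @param a0 equatorial cell area, km^2.
#' @return List of named scalars (shares in percent, masses in Mt C, areas
#'   in km^2, residence time in days).
#' @export
global_summary <- function(class_grids, bathymetry,
                           poc_flux_Mt_day = (3.76 + 3.91) / 2,
                           burial_Mt_day = 0.82, a0 = 12343) {
  total_grid <- combine_classes(class_grids)
  total <- global_integral(total_grid, a0)
  per_class <- vapply(class_grids, global_integral, numeric(1), a0 = a0)
  shares <- 100 * per_class / total
  names(shares) <- paste0("share_", names(class_grids), "_pct")

  area_all <- ocean_area_km2(bathymetry, a0)
  d <- bathymetry$values
  area <- matrix(cell_area_km2(bathymetry$lat, a0), nrow(d), ncol(d))
  v <- total_grid$values
  mass_cell <- ifelse(is.na(v), 0, v) * area * 1e6 / 1e15
  shelf <- !is.na(d) & d <= 200
  deep <- !is.na(d) & d > 3000
  latm <- matrix(bathymetry$lat, nrow(d), ncol(d))
  polar <- !is.na(d) & abs(latm) > 60
  tropic <- !is.na(d) & abs(latm) < 23.5
  pct_mass <- function(mask) 100 * sum(mass_cell[mask & !is.na(v)]) / total
  pct_area <- function(mask) 100 * sum(area[mask]) / area_all

  c(list(total_Mt = total), as.list(shares), list(
    shelf_biomass_pct = pct_mass(shelf), shelf_area_pct = pct_area(shelf),
    deep3000_biomass_pct = pct_mass(deep), deep3000_area_pct = pct_area(deep),
    polar_biomass_pct = pct_mass(polar), polar_area_pct = pct_area(polar),
    tropical_biomass_pct = pct_mass(tropic), tropical_area_pct = pct_area(tropic),
    ocean_area_km2 = area_all,
    residence_time_days = residence_time(total, poc_flux_Mt_day, burial_Mt_day)
  ))
}
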