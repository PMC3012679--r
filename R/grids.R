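# Lightweight global raster container shared by the generator, the predictor
# extraction, and the mapping stages. Values are stored as an n_lat x n_lon
# matrix with rows ordered south to north; cell centers sit on half-degree
# multiples for the default 1-degree lattice. Land cells are NA and excluded
# from every sum.

#' Construct a global lat/lon grid
#'
#' @param values numeric matrix, `n_lat` rows (south to north) by `n_lon`
#'   columns (west to east, from -180); `NA` marks land / no data.
#' @param name short variable name.
#' @param units unit string.
#' @return Object of class `world_grid` with fields `values`, `lat`, `lon`
#'   (cell-center coordinates), `name`, `units`.
#' @export
world_grid <- function(values, name = "value", units = "") {
  values <- as.matrix(values)
  n_lat <- nrow(values); n_lon <- ncol(values)
  if (n_lat < 1 || n_lon < 1) stopf("grid must have positive dimensions")
  structure(list(
    values = values,
    lat = grid_centers(n_lat, -90, 90),
    lon = grid_centers(n_lon, -180, 180),
    name = name, units = units
  ), class = "world_grid")
}

grid_centers <- function(n, lo, hi) {
  step <- (hi - lo) / n
  lo + step * (seq_len(n) - 0.5)
}

#' @export
print.world_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("world_grid '%s' [%s]: %d x %d cells, %d ocean (%.1f%%), range %s\n",
              x$name, x$units, nrow(v), ncol(v), sum(!is.na(v)),
              100 * mean(!is.na(v)),
              if (all(is.na(v))) "all NA"
              else paste(signif(range(v, na.rm = TRUE), 4), collapse = " to ")))
  invisible(x)
}

# row/column indices of the cell containing (lat, lon); lon wrapped to [-180, 180)
grid_cell_index <- function(grid, lat, lon) {
  n_lat <- nrow(grid$values); n_lon <- ncol(grid$values)
  lon <- ((lon + 180) %% 360) - 180
  i <- pmin(pmax(floor((lat + 90) / (180 / n_lat)) + 1, 1), n_lat)
  j <- pmin(pmax(floor((lon + 180) / (360 / n_lon)) + 1, 1), n_lon)
  cbind(i, j)
}

# Mean of a box of `box` x `box` cells centered on cell (i, j), NA cells
# ignored. Longitude wraps across the dateline; latitude truncates at the
# poles. Returns NA if every cell in the box is NA.
grid_box_mean <- function(grid, i, j, box = 1) {
  if (box == 1) return(grid$values[i, j])
  h <- (box - 1) %/% 2
  n_lat <- nrow(grid$values); n_lon <- ncol(grid$values)
  ii <- (i - h):(i + h)
  ii <- ii[ii >= 1 & ii <= n_lat]
  jj <- ((j - h):(j + h) - 1) %% n_lon + 1
  vals <- grid$values[ii, jj, drop = FALSE]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# elementwise transform keeping metadata
grid_map <- function(grid, f, name = grid$name, units = grid$units) {
  g <- grid
  g$values <- f(grid$values)
  g$name <- name; g$units <- units
  g
}

#' Write a grid as long-format CSV
#'
#' Columns `lat`, `lon`, `value`; land (NA) cells are omitted.
#'
#' @param grid a `world_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  idx <- which(!is.na(grid$values), arr.ind = TRUE)
  df <- data.frame(lat = grid$lat[idx[, 1]], lon = grid$lon[idx[, 2]],
                   value = grid$values[idx])
  df <- df[order(df$lat, df$lon), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV grid
#'
#' Inverse of [write_grid_csv()]: cells absent from the file are NA.
#'
#' @param path CSV with columns `lat`, `lon`, `value`.
#' @param n_lat,n_lon lattice dimensions (default 1-degree global).
#' @param name,units metadata for the resulting grid.
#' @return A `world_grid`.
#' @export
read_grid_csv <- function(path, n_lat = 180, n_lon = 360, name = "value", units = "") {
  df <- read.csv(path)
  if (!all(c("lat", "lon", "value") %in% names(df)))
    stopf("grid CSV must have columns lat, lon, value")
  g <- world_grid(matrix(NA_real_, n_lat, n_lon), name = name, units = units)
  ij <- grid_cell_index(g, df$lat, df$lon)
  g$values[ij] <- df$value
  g
}
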