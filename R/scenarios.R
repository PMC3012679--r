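# Predictor extraction at record locations, the satellite-coverage data
# selection scenarios, per-dataset forest ensembles, and cross-class
# importance combination.

# NA-aware neighborhood (box x box) mean of a grid, as a full matrix.
# Longitude wraps across the dateline; latitude truncates at the poles.
box_mean_matrix <- function(values, box) {
  if (box == 1) return(values)
  h <- (box - 1) %/% 2
  n_lat <- nrow(values); n_lon <- ncol(values)
  v0 <- ifelse(is.na(values), 0, values)
  m0 <- !is.na(values)
  sumv <- matrix(0, n_lat, n_lon); cnt <- matrix(0, n_lat, n_lon)
  for (di in -h:h) {
    ii <- seq_len(n_lat) + di
    keep <- ii >= 1 & ii <= n_lat
    for (dj in -h:h) {
      jj <- (seq_len(n_lon) - 1 + dj) %% n_lon + 1
      sv <- matrix(0, n_lat, n_lon); sc <- matrix(0, n_lat, n_lon)
      sv[keep, ] <- v0[ii[keep], jj, drop = FALSE]
      sc[keep, ] <- m0[ii[keep], jj, drop = FALSE]
      sumv <- sumv + sv; cnt <- cnt + sc
    }
  }
  out <- sumv / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Extract environmental predictors at record locations
#'
#' For each record and each of the 39 predictors, takes the mean of the
#' declared extraction box (3x3 cells for the satellite productivity fields,
#' 1x1 otherwise) centered on the record's grid cell, ignoring NA (land)
#' cells; boxes wrap across the dateline and truncate at the poles. The
#' months-of-coverage value at the record's cell is attached (records on
#' cells without coverage are treated as coverage 0).
#'
#' @param records record data.frame.
#' @param world a `synthetic_world` (or any list with `grids` and `coverage`
#'   `world_grid`s).
#' @param box_sizes named integer vector of box sizes per predictor
#'   (defaults to the declared catalogue).
#' @return List of class `predictor_table`: `X` (n x 39 matrix),
#'   `coverage` (months per record), `records`, `box_sizes`, and
#'   `n_missing` (records with at least one all-NA box).
#' @export
extract_predictors <- function(records, world,
                               box_sizes = predictor_box_sizes()) {
  grids <- world$grids
  miss <- setdiff(names(grids), names(box_sizes))
  if (length(miss)) stopf("no box size declared for: %s", paste(miss, collapse = ", "))
  g1 <- grids[[1]]
  ij <- grid_cell_index(g1, records$latitude, records$longitude)
  X <- matrix(NA_real_, nrow(records), length(grids),
              dimnames = list(NULL, names(grids)))
  for (nm in names(grids)) {
    bm <- box_mean_matrix(grids[[nm]]$values, box_sizes[[nm]])
    X[, nm] <- bm[ij]
  }
  cov <- world$coverage$values[ij]
  cov[is.na(cov)] <- 0
  structure(list(X = X, coverage = as.numeric(cov), records = records,
                 box_sizes = box_sizes,
                 n_missing = sum(!complete.cases(X))),
            class = "predictor_table")
}

#' Filter a predictor table by satellite coverage
#'
#' Keeps records whose productivity predictors were computed from more than
#' `threshold_months` months of satellite measurements. Threshold 0 keeps
#' everything; the strictest threshold (90) removes most high-latitude
#' records, where winter darkness and cloud cover limit ocean-color
#' coverage.
#'
#' @param table a `predictor_table` from [extract_predictors()].
#' @param threshold_months one of 0, 30, 60, 90.
#' @return The filtered `predictor_table`.
#' @export
apply_scenario <- function(table, threshold_months) {
  stopifnot(inherits(table, "predictor_table"))
  keep <- table$coverage > threshold_months
  out <- table
  out$X <- table$X[keep, , drop = FALSE]
  out$coverage <- table$coverage[keep]
  out$records <- table$records[keep, , drop = FALSE]
  out$n_missing <- sum(!complete.cases(out$X))
  out
}

#' Fit the four-scenario forest ensemble for one dataset
#'
#' Log10-transforms the chosen response for one size class, extracts
#' predictors, and fits one random forest per coverage scenario (all data,
#' then > 30, > 60, > 90 months). Model performance (OOB R^2) and
#' accuracy importance are aggregated as mean and SD across the scenarios to
#' measure sensitivity to the loss of high-latitude data.
#'
#' @param records record data.frame (or a `synthetic_world` whose records
#'   are used).
#' @param world the `synthetic_world` holding the predictor grids.
#' @param response `"biomass"` or `"abundance"`.
#' @param class size class to model.
#' @param n_trees trees per forest (default 1000).
#' @param seed integer seed; each scenario forest gets a derived sub-seed.
#' @param predictors optional character subset of predictor columns.
#' @param thresholds coverage thresholds (default `c(0, 30, 60, 90)`).
#' @param min_records scenarios left with fewer records are skipped with a
#'   flag (default 30).
#' @param mtry,min_leaf forest hyperparameters (defaults: `ceiling(p/3)`, 5).
#' @param reseed_scenarios give each scenario its own RNG stream (restart
#'   mode). Default FALSE: all scenarios share one derived seed, so
#'   scenarios holding identical data produce identical forests and the
#'   ensemble SD isolates the effect of the data selection alone.
#' @return Object of class `scenario_ensemble`: per-scenario fits (`n`,
#'   `r2`, `model`, `importance`), `r2_mean`, `r2_sd`, aggregated
#'   `importance` (mean and SD per predictor across scenarios), and flags.
#' @export
run_simulations <- function(records, world, response = c("biomass", "abundance"),
                            class = "macrofauna", n_trees = 1000, seed = 1,
                            predictors = NULL, thresholds = c(0, 30, 60, 90),
                            min_records = 30, mtry = NULL, min_leaf = 5,
                            reseed_scenarios = FALSE) {
  response <- match.arg(response)
  if (inherits(records, "synthetic_world")) records <- records$records
  col <- if (response == "biomass") "biomass_mgC_m2" else "abundance_per_m2"
  rec <- records[records$size_class == class & !is.na(records[[col]]) &
                   records[[col]] > 0, , drop = FALSE]
  if (nrow(rec) < min_records)
    stopf("only %d usable %s records for %s", nrow(rec), response, class)
  tab <- extract_predictors(rec, world)
  if (!is.null(predictors)) {
    bad <- setdiff(predictors, colnames(tab$X))
    if (length(bad)) stopf("unknown predictor(s): %s", paste(bad, collapse = ", "))
    tab$X <- tab$X[, predictors, drop = FALSE]
  }
  keep <- complete.cases(tab$X)
  if (any(!keep)) {
    tab$X <- tab$X[keep, , drop = FALSE]
    tab$coverage <- tab$coverage[keep]
    tab$records <- tab$records[keep, , drop = FALSE]
  }

  scenarios <- list(); flagged <- character(0)
  for (k in seq_along(thresholds)) {
    th <- thresholds[k]
    sc <- apply_scenario(tab, th)
    if (nrow(sc$X) < min_records) {
      flagged <- c(flagged, sprintf("scenario >%d months skipped (n = %d)", th, nrow(sc$X)))
      next
    }
    y <- log10(sc$records[[col]])
    sk <- if (reseed_scenarios) k else 1L
    model <- fit_forest(sc$X, y, n_trees = n_trees, mtry = mtry,
                        min_leaf = min_leaf, seed = derive_seed(seed, sk))
    scenarios[[length(scenarios) + 1]] <- list(
      threshold = th, n = nrow(sc$X), model = model,
      r2 = as.numeric(oob_r2(model)),
      importance = permutation_importance(model, seed = derive_seed(seed, 100 + sk)))
  }
  if (!length(scenarios)) stopf("no scenario retained enough records")
  if (length(flagged)) warnf(paste(flagged, collapse = "; "))

  r2 <- vapply(scenarios, `[[`, numeric(1), "r2")
  pn <- scenarios[[1]]$model$predictor_names
  imp_mat <- vapply(scenarios, function(s) {
    setNames(s$importance$mean_increase_mse, s$importance$predictor)[pn]
  }, numeric(length(pn)))
  imp_mat <- matrix(imp_mat, nrow = length(pn),
                    dimnames = list(pn, NULL))
  importance <- data.frame(
    predictor = pn,
    mean_increase_mse = rowMeans(imp_mat),
    sd_increase_mse = apply(imp_mat, 1, function(z) if (length(z) > 1) sd(z) else 0),
    stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_increase_mse), ]
  rownames(importance) <- NULL

  structure(list(
    response = response, class = class, thresholds = thresholds,
    scenarios = scenarios, flagged = flagged,
    n = vapply(scenarios, `[[`, numeric(1), "n"),
    r2 = r2, r2_mean = mean(r2), r2_sd = if (length(r2) > 1) sd(r2) else 0,
    importance = importance, importance_matrix = imp_mat,
    predictors = pn, seed = seed
  ), class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf("scenario_ensemble: %s %s, %d scenario(s)\n", x$class, x$response,
              length(x$scenarios)))
  cat(sprintf("  n = %s; R^2 = %s (mean %.3f, SD %.4f)\n",
              paste(x$n, collapse = "/"),
              paste(sprintf("%.3f", x$r2), collapse = "/"), x$r2_mean, x$r2_sd))
  cat("  top predictors:", paste(head(x$importance$predictor, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Combine predictor importance across size classes
#'
#' Pools the per-scenario accuracy importance of the biomass models for
#' bacteria, meiofauna, macrofauna, and megafauna — legitimate because all
#' four share the mg C m-2 currency — and reports the mean and SD per
#' predictor over all (class, scenario) runs, top `n_top` descending.
#' Abundance ensembles are refused (cells vs individuals are not a common
#' currency).
#'
#' @param ensembles list of `scenario_ensemble`s fitted on biomass.
#' @param n_top rows in the report (default 20).
#' @return data.frame `predictor`, `mean_increase_mse`, `sd_increase_mse`,
#'   `rank`.
#' @export
combine_importance <- function(ensembles, n_top = 20) {
  if (inherits(ensembles, "scenario_ensemble")) ensembles <- list(ensembles)
  for (e in ensembles) {
    stopifnot(inherits(e, "scenario_ensemble"))
    if (e$response != "biomass")
      stopf("combine_importance pools biomass models only (got '%s' for %s)",
            e$response, e$class)
  }
  pn <- ensembles[[1]]$predictors
  mats <- lapply(ensembles, function(e) {
    if (!identical(e$predictors, pn)) stopf("ensembles use different predictor sets")
    e$importance_matrix
  })
  all_runs <- do.call(cbind, mats)
  out <- data.frame(
    predictor = pn,
    mean_increase_mse = rowMeans(all_runs),
    sd_increase_mse = apply(all_runs, 1, function(z) if (length(z) > 1) sd(z) else 0),
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_increase_mse), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  head(out, n_top)
}

#' Reduced ensemble: productivity predictors and depth only
#'
#' Refits the scenario ensemble using only the 18 surface-productivity
#' variables plus water depth (19 predictors) — the satellite-observable
#' subset. Comparison with the full model shows how much of the stock
#' variance the ocean-color/depth predictors alone explain.
#'
#' @inheritParams run_simulations
#' @param ... passed to [run_simulations()].
#' @return A `scenario_ensemble` fitted on the 19-predictor set.
#' @export
reduced_model <- function(records, world, response = c("biomass", "abundance"),
                          class = "macrofauna", ...) {
  run_simulations(records, world, response = response, class = class,
                  predictors = c(productivity_vars(), "depth"), ...)
}

#' Write ensemble summaries as CSV
#'
#' @param ensemble a `scenario_ensemble`.
#' @param summary_path CSV of (scenario threshold, n, R^2).
#' @param importance_path CSV of importance (mean, SD) sorted descending.
#' @return Invisibly, the paths written.
#' @export
write_ensemble_csv <- function(ensemble, summary_path, importance_path) {
  s <- data.frame(threshold_months = vapply(ensemble$scenarios, `[[`, numeric(1), "threshold"),
                  n = ensemble$n, r2 = ensemble$r2)
  write.csv(s, summary_path, row.names = FALSE)
  write.csv(ensemble$importance, importance_path, row.names = FALSE)
  invisible(c(summary_path, importance_path))
}
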