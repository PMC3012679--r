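# Regression random forest: bootstrap-resampled, un-pruned CART trees with
# random predictor subsetting, out-of-bag (OOB) error, and accuracy-based
# permutation importance. The ensemble machinery is implemented here (tree
# growth in compiled code, see src/forest.cpp); nothing is delegated to an
# external forest library.

#' Fit a regression random forest
#'
#' Grows `n_trees` un-pruned regression trees. Each tree is trained on a
#' bootstrap resample of the data (n draws with replacement, so roughly 2/3 of
#' distinct samples are in-bag and the remaining ~1/3 are out-of-bag); at every
#' node the best binary split is chosen over a fresh random subset of `mtry`
#' predictors by maximising the reduction in residual sum of squares. Split
#' thresholds are midpoints between consecutive distinct predictor values; ties
#' are broken towards the lowest predictor index and then the lowest threshold
#' so a fit is a pure function of (data, hyperparameters, seed).
#'
#' @param X numeric matrix (n x p) of predictors; no missing values.
#' @param y numeric response vector of length n.
#' @param n_trees number of trees (default 1000).
#' @param mtry predictors tried at each split; default `ceiling(p/3)`.
#' @param min_leaf minimum samples in a terminal node (default 5).
#' @param seed integer seed fixing bootstrap draws and predictor subsets.
#' @param sampling `"bootstrap"` (default) resamples n with replacement;
#'   `"subsample"` draws an exact 2/3 fraction without replacement; `"none"`
#'   puts every sample in-bag for every tree (no OOB data; useful for
#'   comparing a single tree against exhaustive CART).
#' @return An object of class `rf_forest`: the trees, per-tree in-bag counts,
#'   training data, and hyperparameters.
#' @export
fit_forest <- function(X, y, n_trees = 1000, mtry = NULL, min_leaf = 5,
                       seed = 1, sampling = c("bootstrap", "subsample", "none")) {
  sampling <- match.arg(sampling)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 5) stopf("need at least 5 samples, got %d", n)
  if (p < 1) stopf("need at least 1 predictor")
  if (length(y) != n) stopf("length(y) = %d does not match nrow(X) = %d", length(y), n)
  if (anyNA(X)) stopf("missing values in predictor matrix are not allowed")
  if (anyNA(y)) stopf("missing values in response are not allowed")
  if (n_trees < 1) stopf("n_trees must be >= 1")
  mtry <- as.integer(mtry %||% ceiling(p / 3))
  if (mtry < 1 || mtry > p) stopf("mtry must be in [1, %d]", p)
  min_leaf <- max(1L, as.integer(min_leaf))

  n_bag <- if (sampling == "bootstrap") n else max(1L, round(2 * n / 3))
  replace <- sampling == "bootstrap"
  model <- with_seed(seed, {
    inbag <- if (sampling == "none") {
      replicate(n_trees, seq_len(n), simplify = FALSE)
    } else {
      lapply(seq_len(n_trees), function(t)
        sort(sample.int(n, n_bag, replace = replace)))
    }
    trees <- rf_fit_cpp(X, y, inbag, mtry, min_leaf)
    counts <- vapply(inbag, function(ix) tabulate(ix, nbins = n), integer(n))
    list(trees = trees, inbag_count = counts)
  })
  structure(list(
    trees = model$trees,
    inbag_count = model$inbag_count,   # n x n_trees
    n_trees = as.integer(n_trees), mtry = mtry, min_leaf = min_leaf,
    seed = seed, sampling = sampling,
    X = X, y = y,
    predictor_names = colnames(X) %||% paste0("x", seq_len(p)),
    y_mean = mean(y),
    y_var = mean((y - mean(y))^2),     # population variance, as in OOB R^2
    constant_response = isTRUE(all(y == y[1]))
  ), class = "rf_forest")
}

#' @export
print.rf_forest <- function(x, ...) {
  cat(sprintf("Regression random forest: %d trees, mtry = %d, min_leaf = %d, n = %d, p = %d\n",
              x$n_trees, x$mtry, x$min_leaf, nrow(x$X), ncol(x$X)))
  r2 <- tryCatch(oob_r2(x), error = function(e) NA_real_)
  if (!is.na(r2)) cat(sprintf("OOB R^2 = %.3f (%.1f%% variance explained)\n", r2, 100 * r2))
  invisible(x)
}

#' Out-of-bag predictions
#'
#' The prediction for training sample i averages only the trees for which i
#' was not drawn into the bootstrap (out-of-bag). Samples that were in-bag in
#' every tree (essentially impossible for more than a few dozen trees) get
#' `NA` with a warning.
#'
#' @param model an `rf_forest`.
#' @param X the training predictor matrix; defaults to the matrix stored in
#'   the model and must be identical in shape.
#' @return data.frame with `pred` (OOB mean prediction) and `n_oob_trees`.
#' @export
oob_predict <- function(model, X = model$X) {
  stopifnot(inherits(model, "rf_forest"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (!identical(dim(X), dim(model$X)))
    stopf("X (%d x %d) does not match the training matrix (%d x %d)",
          nrow(X), ncol(X), nrow(model$X), ncol(model$X))
  res <- rf_oob_cpp(model$trees, X, model$inbag_count)
  if (any(res$n_oob_trees == 0))
    warnf("%d sample(s) were in-bag in every tree; OOB prediction is NA",
          sum(res$n_oob_trees == 0))
  data.frame(pred = res$pred, n_oob_trees = res$n_oob_trees)
}

#' Out-of-bag R-squared
#'
#' Percent variance explained, computed as `1 - MSE_OOB / var(y)` where
#' `MSE_OOB` is the mean squared error between observations and aggregated
#' OOB predictions and `var(y)` is the (population) variance of the observed
#' response. Can be negative when the forest predicts worse than the mean.
#'
#' @param model an `rf_forest`.
#' @param y response; defaults to the training response.
#' @return numeric R^2 (fraction). For a constant response the quantity is
#'   undefined; 0 is returned with attribute `undefined = TRUE` and a warning.
#' @export
oob_r2 <- function(model, y = model$y) {
  stopifnot(inherits(model, "rf_forest"))
  if (model$y_var == 0 || isTRUE(model$constant_response)) {
    warnf("response variance is zero; OOB R^2 is undefined (reported as 0)")
    return(structure(0, undefined = TRUE))
  }
  oob <- oob_predict(model)
  ok <- !is.na(oob$pred)
  mse <- mean((y[ok] - oob$pred[ok])^2)
  1 - mse / mean((y - mean(y))^2)
}

#' Accuracy-based permutation importance
#'
#' For each tree and each predictor j: compute the tree's MSE on its own OOB
#' samples, randomly permute predictor j among those OOB samples, recompute
#' the MSE, and record the increase. The report averages the increase over the
#' forest (mean increase of OOB MSE) with its SD across trees. A constant
#' predictor has importance exactly 0 (permutation cannot change it).
#'
#' @param model an `rf_forest`.
#' @param X,y training data; default to what the model stores.
#' @param seed seed for the permutations.
#' @param n_rep permutations per (tree, predictor), averaged (default 1).
#' @return data.frame of class `rf_importance` with columns `predictor`,
#'   `mean_increase_mse`, `sd_increase_mse`, sorted descending by mean.
#' @export
permutation_importance <- function(model, X = model$X, y = model$y,
                                   seed = model$seed, n_rep = 1) {
  stopifnot(inherits(model, "rf_forest"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  per_tree <- with_seed(derive_seed(seed, 104729),
    rf_perm_importance_cpp(model$trees, X, as.numeric(y),
                           model$inbag_count, as.integer(n_rep)))
  out <- data.frame(
    predictor = model$predictor_names,
    mean_increase_mse = rowMeans(per_tree, na.rm = TRUE),
    sd_increase_mse = apply(per_tree, 1, sd, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean_increase_mse), ]
  rownames(out) <- NULL
  attr(out, "per_tree") <- per_tree
  class(out) <- c("rf_importance", "data.frame")
  out
}

#' Predict from a fitted forest
#'
#' @param object an `rf_forest`.
#' @param newdata numeric matrix with the same predictors (columns) as the
#'   training matrix. Rows containing `NA` predict `NA`.
#' @param ... unused.
#' @return numeric vector: the mean over all trees' leaf means (therefore
#'   bounded by the range of the training response).
#' @export
predict.rf_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$X))
    stopf("newdata has %d columns; the forest was trained on %d",
          ncol(newdata), ncol(object$X))
  rf_predict_cpp(object$trees, newdata)
}

#' Serialize a forest to JSON lines
#'
#' Writes one JSON object per line: a header (hyperparameters, predictor
#' names) followed by one line per tree (node table). [read_forest_jsonl()]
#' restores a forest that predicts identically; the training data are not
#' stored, so OOB quantities are not available on the restored object.
#'
#' @param model an `rf_forest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forest_jsonl <- function(model, path) {
  stopifnot(inherits(model, "rf_forest"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(type = "rf_forest", n_trees = model$n_trees, mtry = model$mtry,
                 min_leaf = model$min_leaf, seed = model$seed,
                 sampling = model$sampling,
                 predictor_names = model$predictor_names)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (tr in model$trees)
    writeLines(jsonlite::toJSON(list(tree = tr), digits = NA), con)
  invisible(path)
}

#' Read a forest written by [write_forest_jsonl()]
#'
#' @param path file written by [write_forest_jsonl()].
#' @return An `rf_forest` usable with [predict.rf_forest()].
#' @export
read_forest_jsonl <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$type, "rf_forest")) stopf("not an rf_forest JSONL file: %s", path)
  trees <- lapply(lines[-1], function(l) {
    m <- jsonlite::fromJSON(l)$tree
    storage.mode(m) <- "double"
    m
  })
  p <- length(header$predictor_names)
  structure(list(
    trees = trees, inbag_count = NULL,
    n_trees = length(trees), mtry = header$mtry, min_leaf = header$min_leaf,
    seed = header$seed, sampling = header$sampling,
    X = matrix(numeric(0), 0, p, dimnames = list(NULL, header$predictor_names)),
    y = numeric(0),
    predictor_names = header$predictor_names,
    y_mean = NA_real_, y_var = NA_real_, constant_response = FALSE
  ), class = "rf_forest")
}
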