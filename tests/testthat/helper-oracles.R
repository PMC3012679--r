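# Independent oracles used across the suite.

# Exhaustive-search regression CART: at every node, scan all predictors and
# all midpoint thresholds, maximize sum_L^2/n_L + sum_R^2/n_R, same
# strict-improvement guard and (lowest predictor, lowest threshold)
# tie-break as the package's tree grower, but implemented independently in
# plain R. Returns a prediction function.
cart_oracle <- function(X, y, min_leaf = 1) {
  X <- as.matrix(X)
  grow <- function(idx) {
    n <- length(idx)
    mu <- mean(y[idx])
    ss <- sum((y[idx] - mu)^2)
    if (n < 2 * min_leaf || ss <= 0) return(list(leaf = TRUE, value = mu))
    base <- sum(y[idx])^2 / n
    best <- list(score = base, var = NA, thr = NA)
    for (j in seq_len(ncol(X))) {
      ord <- order(X[idx, j])
      xs <- X[idx, j][ord]; ys <- y[idx][ord]
      csum <- cumsum(ys); tot <- csum[n]
      for (i in seq_len(n - 1)) {
        if (i < min_leaf || n - i < min_leaf) next
        if (xs[i] == xs[i + 1]) next
        score <- csum[i]^2 / i + (tot - csum[i])^2 / (n - i)
        if (score > best$score + 1e-10 * abs(base))
          best <- list(score = score, var = j,
                       thr = xs[i] + (xs[i + 1] - xs[i]) / 2)
      }
    }
    if (is.na(best$var)) return(list(leaf = TRUE, value = mu))
    lidx <- idx[X[idx, best$var] <= best$thr]
    ridx <- idx[X[idx, best$var] > best$thr]
    list(leaf = FALSE, var = best$var, thr = best$thr,
         left = grow(lidx), right = grow(ridx))
  }
  tree <- grow(seq_along(y))
  pred1 <- function(node, x) {
    while (!node$leaf) node <- if (x[node$var] <= node$thr) node$left else node$right
    node$value
  }
  function(Xn) apply(as.matrix(Xn), 1, function(x) pred1(tree, x))
}

# Brute-force Fisher-Jenks: enumerate every placement of k-1 cuts and keep
# the partition with minimal total within-class sum of squares. Returns the
# class upper bounds (same convention as jenks_breaks) and the optimal SSD.
jenks_oracle <- function(x, k) {
  x <- sort(x); n <- length(x)
  cuts <- utils::combn(n - 1, k - 1)
  best_ss <- Inf; best <- NULL
  for (c in seq_len(ncol(cuts))) {
    ends <- c(cuts[, c], n)
    starts <- c(1, head(ends, -1) + 1)
    ss <- sum(mapply(function(s, e) sum((x[s:e] - mean(x[s:e]))^2), starts, ends))
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- ends }
  }
  list(breaks = x[best], ssd = best_ss)
}

# Closed-form value of the two-stage (partial-regression) depth slope on a
# fixed dataset, computed by explicit projection algebra rather than lm():
# slope = cov(resid(y | 1, lat, lon), depth) / var(depth).
partial_slope_oracle <- function(y, lat, lon, depth) {
  Z <- cbind(1, lat, lon)
  ry <- y - Z %*% solve(crossprod(Z), crossprod(Z, y))
  sum((depth - mean(depth)) * ry) / sum((depth - mean(depth))^2)
}

# Shared small synthetic world (lazily built once per test run).
.world_cache <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(.world_cache$small)) {
    bathy <- gen_bathymetry(7, n_lat = 36, n_lon = 72)
    .world_cache$small <- gen_predictor_grids(8, bathy)
  }
  .world_cache$small
}

# 1-degree world used by the acceptance-scale checks
full_world <- function() {
  if (is.null(.world_cache$full)) {
    bathy <- gen_bathymetry(42)
    .world_cache$full <- gen_predictor_grids(43, bathy)
  }
  .world_cache$full
}
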