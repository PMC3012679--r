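# Partial-regression depth-trend analysis. Stage 1 removes latitude and
# longitude by ordinary least squares and adds the stage-1 intercept back to
# the residuals so the adjusted response stays on the original scale; stage 2
# regresses the adjusted response on water depth and reports the slope with
# its F test. The same two-stage scheme, with different covariates, drives
# the latitude-parabola analysis.

#' Partial regression of a (log10) stock on depth
#'
#' @param values response vector, typically log10 stock.
#' @param lat,lon covariates removed in stage 1 (degrees). A constant
#'   covariate is dropped (stage 1 collapses toward intercept-only).
#' @param depth stage-2 predictor, meters positive down. Must not be
#'   constant.
#' @param response_name label carried into the fit.
#' @return Object of class `partial_fit`: `n`, stage-1 intercept and lat/lon
#'   coefficients, stage-2 `slope` (per m) and `intercept` (response units),
#'   `F`, `p`, `significant` (at 0.001), `slope_se`, and `r2` of stage 2.
#' @export
partial_regression <- function(values, lat, lon, depth,
                               response_name = "log10 stock") {
  ok <- complete.cases(values, lat, lon, depth) & is.finite(values)
  values <- values[ok]; lat <- lat[ok]; lon <- lon[ok]; depth <- depth[ok]
  n <- length(values)
  if (n < 10) stopf("need at least 10 complete records, have %d", n)
  if (sd(depth) == 0) stopf("depth is constant; slope undefined")

  covs <- list(lat = lat, lon = lon)
  covs <- covs[vapply(covs, function(v) sd(v) > 0, logical(1))]
  s1 <- if (length(covs)) {
    lm(values ~ ., data = as.data.frame(covs))
  } else lm(values ~ 1)
  adjusted <- resid(s1) + coef(s1)[["(Intercept)"]]

  s2 <- lm(adjusted ~ depth)
  sm <- summary(s2)
  Fstat <- unname(sm$fstatistic["value"])
  p <- pf(Fstat, sm$fstatistic["numdf"], sm$fstatistic["dendf"], lower.tail = FALSE)
  structure(list(
    response = response_name, n = n,
    stage1_intercept = unname(coef(s1)[["(Intercept)"]]),
    coef_lat = unname(coef(s1)["lat"]),
    coef_lon = unname(coef(s1)["lon"]),
    intercept = unname(coef(s2)[1]),
    slope = unname(coef(s2)[2]),
    slope_se = sm$coefficients["depth", "Std. Error"],
    F = Fstat, p = unname(p), significant = unname(p) < 0.001,
    r2 = sm$r.squared
  ), class = "partial_fit")
}

#' @export
print.partial_fit <- function(x, ...) {
  cat(sprintf("%s (n = %d): %s;  F = %.4g, %s\n",
              x$response, x$n, format_equation(x),
              x$F, if (x$significant) "P < 0.001" else "n.s."))
  invisible(x)
}

#' Format a depth regression as an equation string
#'
#' @param fit a `partial_fit`.
#' @return Character like `"Y = 3.05-(5.15e-04) X"` (Y the adjusted log10
#'   response, X depth in m).
#' @export
format_equation <- function(fit) {
  sgn <- if (fit$slope < 0) "-" else "+"
  sprintf("Y = %.3g%s(%.3g) X", fit$intercept, sgn, abs(fit$slope))
}

#' Depth regressions for every size class and response
#'
#' Runs [partial_regression()] of log10 biomass, log10 abundance, and log10
#' body size (biomass/abundance, via [body_size()]) against depth for each
#' size class with enough records. Non-positive stock values cannot be
#' log-transformed and are dropped per fit; classes with fewer than `min_n`
#' usable records are skipped with a diagnostic.
#'
#' @param records record data.frame.
#' @param min_n minimum records per fit (default 10).
#' @return data.frame with one row per (response, class): `n`, `intercept`,
#'   `slope`, `slope_se`, `F`, `p`, `significant`, `equation`. Skipped
#'   combinations are listed in attribute `"skipped"`.
#' @export
fit_all_classes <- function(records, min_n = 10) {
  responses <- list(
    biomass = function(r) r$biomass_mgC_m2,
    abundance = function(r) r$abundance_per_m2,
    body_size = function(r) as.numeric(body_size(r$biomass_mgC_m2, r$abundance_per_m2))
  )
  rows <- list(); skipped <- character(0)
  for (resp in names(responses)) {
    for (cl in intersect(size_classes(), unique(records$size_class))) {
      r <- records[records$size_class == cl, , drop = FALSE]
      v <- responses[[resp]](r)
      keep <- !is.na(v) & v > 0
      if (sum(keep) < min_n) {
        skipped <- c(skipped, sprintf("%s/%s (n = %d)", resp, cl, sum(keep)))
        next
      }
      fit <- partial_regression(log10(v[keep]), r$latitude[keep],
                                r$longitude[keep], r$depth_m[keep],
                                response_name = sprintf("log10 %s (%s)", resp, cl))
      rows[[length(rows) + 1]] <- data.frame(
        response = resp, size_class = cl, n = fit$n,
        intercept = fit$intercept, slope = fit$slope, slope_se = fit$slope_se,
        F = fit$F, p = fit$p, significant = fit$significant,
        equation = format_equation(fit), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(response = character(0), size_class = character(0), n = integer(0),
               intercept = numeric(0), slope = numeric(0), slope_se = numeric(0),
               F = numeric(0), p = numeric(0), significant = logical(0),
               equation = character(0), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Latitude-parabola partial fit
#'
#' Tests for elevated stocks at high latitudes once depth and longitude are
#' held constant: stage 1 removes depth and longitude (intercept added back),
#' stage 2 regresses the adjusted response on latitude and latitude squared.
#' A "positive parabola" (higher stocks toward both poles) means a positive
#' quadratic coefficient.
#'
#' @param values response vector (log10 stock).
#' @param depth,lon stage-1 covariates.
#' @param lat latitude in degrees; must not be constant.
#' @return List: `coef_lat`, `coef_lat2`, `r2`, `F`, `p`,
#'   `positive_parabola`, `n`.
#' @export
latitude_parabola <- function(values, depth, lon, lat) {
  ok <- complete.cases(values, depth, lon, lat) & is.finite(values)
  values <- values[ok]; depth <- depth[ok]; lon <- lon[ok]; lat <- lat[ok]
  n <- length(values)
  if (n < 10) stopf("need at least 10 complete records, have %d", n)
  if (sd(lat) == 0) stopf("latitude is constant; quadratic fit undefined")
  covs <- list(depth = depth, lon = lon)
  covs <- covs[vapply(covs, function(v) sd(v) > 0, logical(1))]
  s1 <- if (length(covs)) lm(values ~ ., data = as.data.frame(covs)) else lm(values ~ 1)
  adjusted <- resid(s1) + coef(s1)[["(Intercept)"]]
  s2 <- lm(adjusted ~ lat + I(lat^2))
  sm <- summary(s2)
  Fstat <- unname(sm$fstatistic["value"])
  p <- unname(pf(Fstat, sm$fstatistic["numdf"], sm$fstatistic["dendf"],
                 lower.tail = FALSE))
  list(coef_lat = unname(coef(s2)["lat"]),
       coef_lat2 = unname(coef(s2)["I(lat^2)"]),
       lat2_p = sm$coefficients["I(lat^2)", "Pr(>|t|)"],
       r2 = sm$r.squared, F = Fstat, p = p,
       positive_parabola = unname(coef(s2)["I(lat^2)"]) > 0 && p < 0.001,
       n = n)
}

#' Write a depth-regression results table as CSV
#'
#' Mirrors the customary presentation: one row per (response, class) with
#' the equation string, sample size, F statistic, and significance marker.
#'
#' @param fits output of [fit_all_classes()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_trend_table <- function(fits, path) {
  out <- data.frame(
    response = fits$response, size_class = fits$size_class,
    equation = fits$equation, N = fits$n, F = signif(fits$F, 4),
    significance = ifelse(fits$significant, "***", "n.s."))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
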