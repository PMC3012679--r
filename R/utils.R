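#' @useDynLib benthicstocks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef resid fitted var sd anova pf predict quantile
#'   rnorm runif complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a distinct sub-seed; kept < 2^31 so it is a valid R integer seed
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Size classes recognised by the package
#'
#' The operational benthic size categories used throughout: bacteria (cells),
#' meiofauna and macrofauna (small sieved infauna), megafauna (trawl/photo
#' epifauna, invertebrates plus fishes), and the separate invertebrates and
#' fishes subsets of the megafauna.
#'
#' @return Character vector of the six class names.
#' @export
size_classes <- function() {
  c("bacteria", "meiofauna", "macrofauna", "megafauna", "invertebrates", "fishes")
}

# the four classes whose biomass shares a carbon currency and is combined
major_classes <- function() c("bacteria", "meiofauna", "macrofauna", "megafauna")
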