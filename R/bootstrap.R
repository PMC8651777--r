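#' Box-Cox power transform with optional Guerrero-style lambda selection
#'
#' Standard convention: `(x^lambda - 1) / lambda`, natural log at
#' `lambda = 0`. When `lambda` is `NULL` it is chosen on `[0, 1]` by
#' minimizing the coefficient of variation of the per-period ratio
#' `sd_i / mean_i^(1 - lambda)` over length-`period` subseries (Guerrero's
#' criterion restricted to the unit interval). Series containing zeros are
#' shifted by half the smallest positive observed value before transforming;
#' the offset is removed again by [boxcox_inverse()]. Negative values are
#' rejected (concentrations are non-negative).
#'
#' @param x Non-negative numeric series.
#' @param lambda Power parameter in `[0, 1]`, or `NULL` to estimate.
#' @param period Subseries length for lambda estimation.
#' @return List with `y` (transformed series), `lambda` and `offset`.
#' @export
boxcox_transform <- function(x, lambda = NULL, period = 12L) {
  if (any(!is.finite(x))) stop("non-finite values in series")
  if (any(x < 0)) stop("negative values: Box-Cox needs a non-negative series")
  offset <- if (any(x == 0)) {
    if (!any(x > 0)) stop("all-zero series cannot be transformed")
    0.5 * min(x[x > 0])
  } else 0
  xs <- x + offset
  if (is.null(lambda)) lambda <- guerrero_lambda(xs, period)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  list(y = y, lambda = lambda, offset = offset)
}

#' @rdname boxcox_transform
#' @param y Transformed series.
#' @param offset Offset used by the forward transform.
#' @export
boxcox_inverse <- function(y, lambda, offset = 0) {
  x <- if (abs(lambda) < 1e-12) exp(y)
  else {
    base <- pmax(lambda * y + 1, 1e-12)  # truncate: keeps replicates positive
    base^(1 / lambda)
  }
  x - offset
}

# Guerrero's CV-of-ratio criterion on lambda in [0, 1]
guerrero_lambda <- function(x, period) {
  k <- floor(length(x) / period)
  if (k < 2) return(1)  # too short to estimate; identity-scale default
  blocks <- matrix(x[seq_len(k * period)], nrow = period)
  mu <- colMeans(blocks)
  s <- apply(blocks, 2, sd)
  cv <- function(lambda) {
    r <- s / mu^(1 - lambda)
    sd(r) / abs(mean(r))
  }
  optimize(cv, c(0, 1))$minimum
}

#' Seasonal-trend decomposition of a weekly series
#'
#' Thin wrapper around [stats::stl()] returning plain vectors. The seasonal
#' window defaults to `"periodic"` (seasonality treated as stable across
#' years). The additive identity `trend + seasonal + remainder = series`
#' holds exactly by construction.
#'
#' @param x Numeric series.
#' @param period Seasonal period (observations per cycle), >= 2.
#' @param s_window STL seasonal window (`"periodic"` or an odd span).
#' @return List of class `stl_decomposition`: `trend`, `seasonal`,
#'   `remainder`, `period`.
#' @export
stl_decompose <- function(x, period, s_window = "periodic") {
  if (length(x) < 2 * period)
    stop(sprintf("series length %d is below 2 x period (%d); cannot decompose",
                 length(x), 2 * period))
  fit <- stl(ts(x, frequency = period), s.window = s_window)
  comp <- fit$time.series
  structure(list(trend = as.numeric(comp[, "trend"]),
                 seasonal = as.numeric(comp[, "seasonal"]),
                 remainder = as.numeric(comp[, "remainder"]),
                 period = period),
            class = "stl_decomposition")
}

#' Moving-block bootstrap resample of a remainder series
#'
#' Draws contiguous blocks of `block_length` uniformly with replacement from
#' all overlapping positions, concatenates enough of them to exceed the
#' series length, discards a random initial offset and trims to the original
#' length. With `block_length = length(remainder)` only one block exists and
#' the input is returned unchanged. Uses R's current RNG stream.
#'
#' @param remainder Numeric series (typically an STL remainder).
#' @param block_length Block size in weeks, in `1..length(remainder)`.
#' @return Resampled series of the same length.
#' @export
moving_block_resample <- function(remainder, block_length) {
  n <- length(remainder)
  b <- as.integer(block_length)
  if (b < 1L || b > n) stop("block_length must be in 1..length(remainder)")
  if (b == n) return(remainder)
  k <- floor(n / b) + 1L                 # total drawn length k*b > n
  starts <- sample.int(n - b + 1L, k, replace = TRUE)
  draw <- unlist(lapply(starts, function(s) remainder[s:(s + b - 1L)]))
  off <- sample.int(length(draw) - n + 1L, 1L) - 1L
  draw[(off + 1L):(off + n)]
}

#' Bootstrap ensemble of a training series (Box-Cox + STL + MBB)
#'
#' Implements the series-resampling step of the bagged-SARIMA pipeline: the
#' series is Box-Cox transformed, decomposed into trend + seasonal +
#' remainder, the remainder is moving-block resampled, and each recomposed
#' series is mapped back through the inverse transform. Replicate 1 is the
#' original series when `include_original` is set. The full-scale study
#' design uses `B = 1000`; the block length default of 24 weeks preserves
#' within-season dependence in a ~260-week weekly training series (it is
#' clamped to the series length for short series).
#'
#' @param x Strictly positive (or non-negative, see [boxcox_transform()])
#'   training series.
#' @param B Number of replicates.
#' @param period Seasonal period for the decomposition.
#' @param block_length Moving-block size in weeks.
#' @param seed Integer seed; the ensemble is deterministic given it.
#' @param include_original Keep the original series as replicate 1.
#' @param lambda Fixed Box-Cox lambda, or `NULL` to estimate.
#' @param s_window STL seasonal window.
#' @return `bootstrap_ensemble`: list with `replicates` (B x n matrix),
#'   `lambda`, `offset`, `block_length`, `seed`, `decomposition`.
#' @export
generate_ensemble <- function(x, B = 1000L, period = 52L, block_length = 24L,
                              seed = 1L, include_original = TRUE,
                              lambda = NULL, s_window = "periodic") {
  if (B < 1L) stop("B must be >= 1")
  n <- length(x)
  block_length <- min(as.integer(block_length), n)
  bc <- boxcox_transform(x, lambda = lambda, period = period)
  dec <- stl_decompose(bc$y, period, s_window = s_window)
  base <- dec$trend + dec$seasonal
  reps <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      if (b == 1L && include_original) return(x)
      z <- base + moving_block_resample(dec$remainder, block_length)
      boxcox_inverse(z, bc$lambda, bc$offset)
    }, numeric(n)))
  })
  structure(list(replicates = reps, lambda = bc$lambda, offset = bc$offset,
                 block_length = block_length, seed = seed,
                 decomposition = dec),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble> B = %d replicates of length %d (lambda = %.3f, block = %d, seed = %d)\n",
              nrow(x$replicates), ncol(x$replicates), x$lambda,
              x$block_length, x$seed))
  invisible(x)
}
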