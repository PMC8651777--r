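# ---- SARIMA fitting, AICc order selection, forecasting -------------------
#
# Order search follows the stepwise Hyndman-Khandakar recipe: seasonal
# differencing D is chosen by the seasonal-strength heuristic, ordinary
# differencing d by repeated KPSS level tests on the seasonally differenced
# series, then (p,q,P,Q) by a stepwise neighbourhood search minimizing the
# bias-corrected AIC. Likelihood work is done by stats::arima.

# safe arima fit; returns NULL on failure
arima_try <- function(y, order, seasonal, period, xreg, method = "CSS-ML",
                      include_mean = TRUE) {
  fit <- tryCatch(
    suppressWarnings(arima(y, order = order,
                           seasonal = list(order = seasonal, period = period),
                           xreg = xreg, method = method,
                           include.mean = include_mean,
                           optim.control = list(maxit = 500))),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$var.coef) &&
      any(!is.finite(fit$var.coef))) return(NULL)
  # predict.Arima re-evaluates call$xreg in the caller's frame; store the
  # value (assigning NULL removes the stale symbol for covariate-free fits)
  if (!is.null(fit)) fit$call$xreg <- xreg
  fit
}

# convolution of polynomial coefficient vectors (lowest order first)
polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Psi weights (MA-infinity coefficients) of a fitted SARIMA model
#'
#' Expands the fitted model's full autoregressive operator — non-seasonal
#' and seasonal AR polynomials times the ordinary and seasonal differencing
#' operators — and its full moving-average operator, and returns the first
#' `h` psi weights. The h-step forecast error is
#' `sum_{j<h} psi_j * eps_{h-j}`, so `sigma * sqrt(cumsum(psi^2))`
#' reproduces the model's forecast standard errors.
#'
#' @param fit An `arima` fit.
#' @param h Number of weights (forecast horizon).
#' @return Numeric vector `psi[1..h]` with `psi[1] = 1`.
#' @export
psi_weights <- function(fit, h) {
  a <- fit$arma  # (p, q, P, Q, m, d, D)
  p <- a[1]; q <- a[2]; P <- a[3]; Q <- a[4]; m <- a[5]; d <- a[6]; D <- a[7]
  cf <- fit$coef
  pick <- function(prefix, k) if (k > 0) unname(cf[paste0(prefix, seq_len(k))]) else numeric(0)
  at_lag_m <- function(coefs) {  # 1 + c1 B^m + c2 B^2m + ...
    out <- 1
    for (cc in coefs) out <- c(out, rep(0, m - 1L), cc)
    out
  }
  ar_poly <- polymul(c(1, -pick("ar", p)), at_lag_m(-pick("sar", P)))
  if (d > 0) for (i in seq_len(d)) ar_poly <- polymul(ar_poly, c(1, -1))
  if (D > 0) for (i in seq_len(D)) ar_poly <- polymul(ar_poly, c(1, rep(0, m - 1L), -1))
  ma_poly <- polymul(c(1, pick("ma", q)), at_lag_m(pick("sma", Q)))
  ar_vec <- -ar_poly[-1]
  ma_vec <- ma_poly[-1]
  if (h == 1L) return(1)
  c(1, stats::ARMAtoMA(ar = ar_vec, ma = ma_vec, lag.max = h - 1L))
}

# one simulated h-step forecast-error path (uses the current RNG stream)
simulate_forecast_error <- function(fit, h) {
  psi <- psi_weights(fit, h)
  eps <- rnorm(h, 0, sqrt(fit$sigma2))
  vapply(seq_len(h), function(i)
    sum(psi[seq_len(i)] * eps[i:1]), numeric(1))
}

# bias-corrected AIC of a fitted arima model; for CSS fits (no ML
# likelihood) the Gaussian profile surrogate n*log(sigma2) + 2k is used,
# comparable across models with identical differencing
arima_aicc <- function(fit) {
  if (is.null(fit)) return(Inf)
  k <- length(fit$coef) + 1  # + innovation variance
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  aic <- if (is.finite(fit$aic)) fit$aic
  else if (is.finite(fit$sigma2) && fit$sigma2 > 0)
    n * log(fit$sigma2) + 2 * k
  else return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' KPSS test statistic for level stationarity
#'
#' Classic KPSS statistic against a constant level, with a Bartlett-window
#' long-run variance estimate at the customary short truncation lag
#' `trunc(3 * sqrt(n) / 13)`. The 5% critical value for the level case is
#' 0.463; values above it indicate a unit root (difference the series).
#'
#' @param y Numeric series.
#' @return The test statistic (scalar).
#' @export
kpss_statistic <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 8) return(0)
  e <- y - mean(y)
  S <- cumsum(e)
  l <- max(0L, trunc(3 * sqrt(n) / 13))
  lrv <- sum(e^2) / n
  if (l > 0) for (j in seq_len(l))
    lrv <- lrv + 2 * (1 - j / (l + 1)) * sum(e[(j + 1):n] * e[1:(n - j)]) / n
  sum(S^2) / (n^2 * lrv)
}

#' Seasonal strength of a series
#'
#' `max(0, 1 - var(remainder) / var(seasonal + remainder))` from an STL
#' decomposition; values near 1 indicate dominant seasonality. Used with the
#' conventional threshold 0.64 to decide one seasonal difference.
#'
#' @param y Numeric series of length >= 2 * period.
#' @param period Seasonal period.
#' @return Strength in `[0, 1]` (0 when the series is too short or constant).
#' @export
seasonal_strength <- function(y, period) {
  if (period < 2 || length(y) < 2 * period) return(0)
  if (sd(y) < 1e-12) return(0)
  dec <- stl_decompose(y, period)
  denom <- var(dec$seasonal + dec$remainder)
  if (denom < 1e-12) return(0)
  max(0, 1 - var(dec$remainder) / denom)
}

#' Choose differencing orders (d, D) for a seasonal series
#'
#' `D = 1` when the seasonal strength exceeds 0.64 (at most one seasonal
#' difference); `d` then grows from 0 while the KPSS level statistic of the
#' (seasonally) differenced series exceeds the 5% critical value 0.463,
#' subject to `d <= max_d` and `d + D <= 3`.
#'
#' @param y Numeric series.
#' @param period Seasonal period (`1` disables seasonal differencing).
#' @param max_d,max_D Caps on the orders.
#' @return List with integers `d` and `D`.
#' @export
choose_differencing <- function(y, period, max_d = 2L, max_D = 1L) {
  D <- if (period >= 2 && max_D >= 1 && length(y) >= 2 * period &&
           seasonal_strength(y, period) >= 0.64) 1L else 0L
  z <- if (D > 0) diff(y, lag = period) else y
  d <- 0L
  while (d < max_d && d + D < 3L && kpss_statistic(z) > 0.463) {
    z <- diff(z)
    d <- d + 1L
  }
  list(d = d, D = D)
}

#' Stepwise AICc selection of a seasonal ARIMA specification
#'
#' Selects `(p,d,q)(P,D,Q)_m` with exogenous regressors by minimizing the
#' bias-corrected AIC. Differencing orders come from
#' [choose_differencing()]; `(p,q,P,Q)` are then found by a stepwise search
#' starting from the usual four initial candidates and moving to the best
#' neighbour (one order changed by one) until no improvement. Ties favour
#' fewer parameters because a candidate must beat the incumbent strictly.
#' The search is deterministic.
#'
#' @param y Training series.
#' @param xreg Matrix of exogenous regressors (or `NULL`).
#' @param m Seasonal period.
#' @param max_p,max_q,max_P,max_Q,max_d,max_D Search caps (seasonal caps are
#'   kept at 1 for weekly data; estimability with ~5 cycles of history).
#' @param method Estimation method for the search: `"CSS-ML"` compares exact
#'   ML likelihoods; `"CSS"` is the fast approximation (conditional
#'   sum-of-squares profile likelihood), useful for long series.
#' @return `sarima_spec`: list with `order`, `seasonal`, `period`, `aicc`,
#'   `coef`, `sigma2`, `include_mean`.
#' @export
select_order <- function(y, xreg = NULL, m = 52L, max_p = 3L, max_q = 3L,
                         max_P = 1L, max_Q = 1L, max_d = 2L, max_D = 1L,
                         method = "CSS-ML") {
  dd <- choose_differencing(y, m, max_d = max_d, max_D = max_D)
  d <- dd$d; D <- dd$D
  include_mean <- (d + D == 0L)
  seasonal_ok <- m >= 2 && length(y) > 2 * m

  cap <- c(p = max_p, q = max_q,
           P = if (seasonal_ok) max_P else 0L,
           Q = if (seasonal_ok) max_Q else 0L)
  key <- function(o) paste(o, collapse = ",")
  tried <- new.env(parent = emptyenv())
  evaluate <- function(o) {
    k <- key(o)
    if (!is.null(tried[[k]])) return(tried[[k]])
    fit <- arima_try(y, order = c(o[["p"]], d, o[["q"]]),
                     seasonal = c(o[["P"]], D, o[["Q"]]), period = m,
                     xreg = xreg, method = method,
                     include_mean = include_mean)
    tried[[k]] <- list(aicc = arima_aicc(fit), order = o)
    tried[[k]]
  }

  starts <- list(c(p = 2L, q = 2L, P = 1L, Q = 1L),
                 c(p = 0L, q = 0L, P = 0L, Q = 0L),
                 c(p = 1L, q = 0L, P = 1L, Q = 0L),
                 c(p = 0L, q = 1L, P = 0L, Q = 1L))
  starts <- lapply(starts, function(o) pmin(o, cap))
  best <- NULL
  for (o in starts) {
    cand <- evaluate(o)
    if (is.null(best) || cand$aicc < best$aicc) best <- cand
  }
  repeat {
    improved <- FALSE
    o <- best$order
    for (nm in names(cap)) for (step in c(-1L, 1L)) {
      oo <- o
      oo[[nm]] <- oo[[nm]] + step
      if (oo[[nm]] < 0L || oo[[nm]] > cap[[nm]]) next
      cand <- evaluate(oo)
      if (cand$aicc < best$aicc - 1e-8) { best <- cand; improved <- TRUE }
    }
    if (!improved) break
  }
  if (!is.finite(best$aicc)) {
    attempted <- ls(tried)
    stop("no SARIMA model converged; attempted (p,q,P,Q) orders: ",
         paste(attempted, collapse = "; "))
  }
  o <- best$order
  fit <- arima_try(y, order = c(o[["p"]], d, o[["q"]]),
                   seasonal = c(o[["P"]], D, o[["Q"]]), period = m,
                   xreg = xreg, method = method, include_mean = include_mean)
  structure(list(order = c(p = o[["p"]], d = d, q = o[["q"]]),
                 seasonal = c(P = o[["P"]], D = D, Q = o[["Q"]]),
                 period = as.integer(m), aicc = best$aicc,
                 coef = if (!is.null(fit)) coef(fit) else NULL,
                 sigma2 = if (!is.null(fit)) fit$sigma2 else NA_real_,
                 include_mean = include_mean),
            class = "sarima_spec")
}

#' @export
print.sarima_spec <- function(x, ...) {
  cat(sprintf("<sarima_spec> (%d,%d,%d)(%d,%d,%d)[%d], AICc = %.2f\n",
              x$order[1], x$order[2], x$order[3],
              x$seasonal[1], x$seasonal[2], x$seasonal[3], x$period, x$aicc))
  invisible(x)
}

#' Fit a SARIMA model with a fixed specification and forecast ahead
#'
#' Maximum-likelihood (or conditional-sum-of-squares) fit of the given
#' specification to one series, followed by a mean-path forecast over the
#' horizon using the supplied future covariates. Used per bootstrap
#' replicate; a non-convergent fit or non-finite forecast returns `NULL` so
#' the caller can drop and log the replicate.
#'
#' @param y Training series (one bootstrap replicate).
#' @param xreg_train,xreg_future Covariate matrices for the training window
#'   and the forecast horizon (observed future weather: the counterfactual
#'   removes the intervention, not the weather).
#' @param spec A `sarima_spec` from [select_order()].
#' @param horizon Forecast length; must match `nrow(xreg_future)`.
#' @param method `"CSS"` (fast; default for replicate refits) or `"CSS-ML"`.
#' @param innovations Add one simulated future-innovation path (via the
#'   model's psi weights) to the mean forecast, turning the replicate into a
#'   draw from the predictive distribution rather than a conditional mean;
#'   used by the bagged ensemble so the percentile bands reflect forecast
#'   noise, not only training-series resampling. Consumes the current RNG
#'   stream.
#' @return Numeric forecast path of length `horizon`, or `NULL` on failure.
#' @export
fit_and_forecast <- function(y, xreg_train, xreg_future, spec,
                             horizon = nrow(xreg_future), method = "CSS",
                             innovations = FALSE) {
  if (!is.null(xreg_future) && nrow(xreg_future) != horizon)
    stop("future covariates must cover all horizon weeks")
  if (sd(y) < 1e-12) {
    # degenerate constant replicate: SARIMA likelihood is singular, and the
    # only sensible forecast is the constant itself
    return(rep(mean(y), horizon))
  }
  fit <- arima_try(y, order = unname(spec$order), seasonal = unname(spec$seasonal),
                   period = spec$period, xreg = xreg_train, method = method,
                   include_mean = spec$include_mean)
  if (is.null(fit)) return(NULL)
  fc <- tryCatch(suppressWarnings(predict(fit, n.ahead = horizon,
                                          newxreg = xreg_future)),
                 error = function(e) NULL)
  if (is.null(fc) || any(!is.finite(fc$pred))) return(NULL)
  path <- as.numeric(fc$pred)
  if (innovations) path <- path + simulate_forecast_error(fit, horizon)
  path
}

#' In-sample one-step fitted values of a SARIMA fit
#'
#' @param y Training series.
#' @param xreg Covariates for the training window.
#' @param spec A `sarima_spec`.
#' @param method Estimation method.
#' @return List with `fitted` (y minus innovations) and the `arima` fit, or
#'   `NULL` on failure.
#' @export
sarima_fitted <- function(y, xreg = NULL, spec, method = "CSS-ML") {
  fit <- arima_try(y, order = unname(spec$order), seasonal = unname(spec$seasonal),
                   period = spec$period, xreg = xreg, method = method,
                   include_mean = spec$include_mean)
  if (is.null(fit)) return(NULL)
  list(fitted = as.numeric(y - residuals(fit)), fit = fit)
}
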