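#' Average replicate forecast paths into a bagged counterfactual
#'
#' The bagged counterfactual for week `i` is the arithmetic mean of the
#' surviving replicate forecasts at week `i`; uncertainty bands are the
#' empirical 2.5% / 97.5% percentiles across replicates. Replicate paths
#' containing non-finite values are dropped; if fewer than
#' `max(2, ceiling(0.5 * B))` paths survive the bagging aborts, reporting
#' the convergence rate.
#'
#' @param paths B x horizon matrix of replicate forecasts (rows with `NA`
#'   mark non-convergent replicates).
#' @param observed Observed concentrations for the same weeks.
#' @param week_start Optional dates of the forecast weeks.
#' @param state,pollutant Labels carried through to the result.
#' @param level Band coverage (default 0.95).
#' @return `counterfactual_forecast`: list with `c_obs`, `c_pred`, `lo`,
#'   `hi`, `paths` (surviving replicates), `n_replicates_surviving`,
#'   `convergence_rate`, `week_start`, `state`, `pollutant`, `level`.
#' @export
bag_forecasts <- function(paths, observed, week_start = NULL, state = "XX",
                          pollutant = "pm25", level = 0.95) {
  paths <- as.matrix(paths)
  if (ncol(paths) != length(observed))
    stop("forecast paths and observed values are misaligned")
  ok <- apply(paths, 1, function(r) all(is.finite(r)))
  B <- nrow(paths)
  if (sum(ok) < max(2, ceiling(0.5 * B)))
    stop(sprintf("only %d of %d replicates converged (%.0f%%); aborting",
                 sum(ok), B, 100 * mean(ok)))
  surv <- paths[ok, , drop = FALSE]
  a <- (1 - level) / 2
  structure(list(c_obs = as.numeric(observed), c_pred = colMeans(surv),
                 lo = apply(surv, 2, quantile, probs = a, names = FALSE),
                 hi = apply(surv, 2, quantile, probs = 1 - a, names = FALSE),
                 paths = surv, n_replicates_surviving = sum(ok),
                 convergence_rate = mean(ok),
                 week_start = week_start %||% seq_len(ncol(surv)),
                 state = state, pollutant = pollutant, level = level),
            class = "counterfactual_forecast")
}

#' @export
print.counterfactual_forecast <- function(x, ...) {
  cat(sprintf("<counterfactual_forecast> %s %s: %d weeks, %d surviving replicates (%.0f%% convergence)\n",
              x$state, x$pollutant, length(x$c_pred),
              x$n_replicates_surviving, 100 * x$convergence_rate))
  invisible(x)
}

#' Bagged-SARIMA counterfactual forecast for one state series
#'
#' End-to-end counterfactual machinery for one state x pollutant: bootstrap
#' the training window ([generate_ensemble()]), fit a SARIMA model with
#' weather covariates to each replicate, forecast the horizon with observed
#' future weather, and bag the replicate paths ([bag_forecasts()]). The
#' intervention date plays no role anywhere in this function: the forecast
#' is agnostic to it by construction, and deviations are assessed only
#' downstream.
#'
#' Under the default `spec_policy = "fixed"` the model orders are selected
#' once on the original training series by AICc and only the coefficients
#' are re-estimated per replicate; `"per_replicate"` re-runs the order
#' search on every replicate (much costlier).
#'
#' @param series A [weekly_series()].
#' @param B Number of bootstrap replicates (study design: 1000).
#' @param block_length Moving-block size in weeks.
#' @param seed Integer seed for the ensemble.
#' @param spec Optional pre-selected `sarima_spec`; selected by
#'   [select_order()] when `NULL`.
#' @param spec_policy `"fixed"` or `"per_replicate"` (see Details).
#' @param include_original Keep the original series as replicate 1.
#' @param refit_method Estimation method for per-replicate refits.
#' @param future_innovations Add a simulated future-innovation path to each
#'   replicate forecast (see [fit_and_forecast()]); with it the replicate
#'   spread approximates the predictive distribution of the counterfactual,
#'   so percentile bands and downstream effect CIs carry forecast noise as
#'   well as training-series resampling uncertainty.
#' @param ... Further arguments passed to [select_order()] (search caps).
#' @return A `counterfactual_forecast` (see [bag_forecasts()]); the selected
#'   spec and policy are attached as fields `spec` and `spec_policy`.
#' @export
counterfactual_forecast <- function(series, B = 1000L, block_length = 24L,
                                    seed = 1L, spec = NULL,
                                    spec_policy = c("fixed", "per_replicate"),
                                    include_original = TRUE,
                                    refit_method = "CSS",
                                    future_innovations = TRUE, ...) {
  spec_policy <- match.arg(spec_policy)
  sp <- series_split(series)
  m <- guess_period(series)
  horizon <- length(sp$y_future)
  ens <- generate_ensemble(sp$y_train, B = B, period = m,
                           block_length = block_length, seed = seed,
                           include_original = include_original)
  if (is.null(spec) && spec_policy == "fixed")
    spec <- select_order(sp$y_train, xreg = sp$xreg_train, m = m, ...)
  paths <- matrix(NA_real_, nrow = B, ncol = horizon)
  spec_outer <- spec
  paths <- with_seed(sub_seed(seed, "future_paths"), {
    for (b in seq_len(B)) {
      yb <- ens$replicates[b, ]
      spec_b <- if (spec_policy == "per_replicate")
        tryCatch(select_order(yb, xreg = sp$xreg_train, m = m, ...),
                 error = function(e) NULL)
      else spec_outer
      if (is.null(spec_b)) next
      fc <- fit_and_forecast(yb, sp$xreg_train, sp$xreg_future, spec_b,
                             horizon = horizon, method = refit_method,
                             innovations = future_innovations)
      if (!is.null(fc)) paths[b, ] <- fc
    }
    paths
  })
  out <- bag_forecasts(paths, sp$y_future, week_start = sp$week_start_future,
                       state = attr(series, "state"),
                       pollutant = attr(series, "pollutant"))
  out$spec <- spec
  out$spec_policy <- spec_policy
  out
}

# seasonal period of a weekly series: prefer an explicit attribute, else 52
guess_period <- function(series) {
  as.integer(attr(series, "period") %||% 52L)
}

#' Set the seasonal period attribute of a weekly series
#'
#' Weekly data has an annual cycle of 52 weeks; desk-scale synthetic runs
#' use shorter cycles. [simulate_state_series()] sets this automatically.
#'
#' @param series A [weekly_series()].
#' @param period Observations per seasonal cycle.
#' @return The series with the attribute set.
#' @export
set_period <- function(series, period) {
  attr(series, "period") <- as.integer(period)
  series
}

#' Hold-out validation run over the final pre-intervention year
#'
#' Applies the identical counterfactual machinery with the split shifted
#' back by one horizon: the last `horizon` training weeks are treated as the
#' forecast period and the weeks before them as training (the study design
#' trains on 2015-2018 and predicts Jan-Apr 2019). The held-out observed
#' weeks never enter the fit: they are the truncated series' forecast
#' segment, and the original forecast period is discarded entirely.
#'
#' @param series A [weekly_series()].
#' @param horizon Validation horizon (default: the series' own horizon).
#' @param ... Passed to [counterfactual_forecast()].
#' @return A `counterfactual_forecast` over the validation weeks.
#' @export
validation_run <- function(series, horizon = forecast_horizon(series), ...) {
  s <- attr(series, "split_index")
  if (s <= horizon + 1)
    stop("training window too short to hold out a validation horizon")
  keep <- seq_len(s)  # drop the true forecast period entirely
  trunc <- weekly_series(series$week_start[keep], series$value[keep],
                         series$temperature[keep], series$precipitation[keep],
                         series$humidity[keep], split_index = s - horizon,
                         state = attr(series, "state"),
                         pollutant = attr(series, "pollutant"))
  trunc <- set_period(trunc, guess_period(series))
  counterfactual_forecast(trunc, ...)
}

#' Full per-state analysis: counterfactual, deviations, intervention effect
#'
#' Convenience pipeline for one state x pollutant: bagged counterfactual
#' ([counterfactual_forecast()], which never sees the intervention date),
#' weekly deviations ([compute_deviations()]), then the before/after effect
#' ([estimate_effect()]) at the intervention week. Model assessment (APE,
#' MASE) is included.
#'
#' @param series A [weekly_series()].
#' @param t_int_week Intervention week index within the forecast period
#'   (from [week_index_of()] for calendar data).
#' @param B,block_length,seed,... Passed to [counterfactual_forecast()].
#' @param t_int_in_after Boundary rule for [effect_windows()].
#' @return List with `forecast`, `deviations`, `effect`, `assessment`.
#' @export
run_state_analysis <- function(series, t_int_week, B = 1000L,
                               block_length = 24L, seed = 1L,
                               t_int_in_after = TRUE, ...) {
  cf <- counterfactual_forecast(series, B = B, block_length = block_length,
                                seed = seed, ...)
  dev <- compute_deviations(cf)
  eff <- estimate_effect(dev, t_int_week, t_int_in_after = t_int_in_after)
  sp <- series_split(series)
  fitted <- sarima_fitted(sp$y_train, sp$xreg_train, cf$spec)
  assessment <- list(
    ape = compute_ape(dev),
    mase = if (is.null(fitted)) NA_real_ else
      compute_mase(fitted$fitted, sp$y_train, sp$y_train))
  list(forecast = cf, deviations = dev, effect = eff,
       assessment = assessment)
}
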