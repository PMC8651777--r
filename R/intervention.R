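#' Weekly deviations between observed and counterfactual concentrations
#'
#' `delta_i = C_obs_i - C_pred_i` for each forecast week, plus the
#' replicate-level deviation matrix (observed minus each surviving replicate
#' path) retained for uncertainty quantification.
#'
#' @param forecast A `counterfactual_forecast` (see [bag_forecasts()]).
#' @return `deviation_series`: list with `delta`, `replicate_deltas`
#'   (B_surv x horizon), `week_start`, `state`, `pollutant`.
#' @export
compute_deviations <- function(forecast) {
  stopifnot(inherits(forecast, "counterfactual_forecast"))
  if (length(forecast$c_obs) != length(forecast$c_pred))
    stop("observed and predicted weeks are misaligned")
  structure(list(delta = forecast$c_obs - forecast$c_pred,
                 replicate_deltas = sweep(-forecast$paths, 2, forecast$c_obs, "+"),
                 week_start = forecast$week_start,
                 state = forecast$state, pollutant = forecast$pollutant),
            class = "deviation_series")
}

#' Intervention effect from before/after deviation medians
#'
#' `delta_before` is the median weekly deviation over the weeks before the
#' intervention, `delta_after` the median over the weeks from the
#' intervention onward, and the effect is their difference
#' `delta_effect = delta_before - delta_after`. Under this sign convention a
#' positive effect means concentrations declined after the intervention.
#' The confidence interval is the percentile interval of the same statistic
#' computed on each bootstrap replicate's deviation series; the effect is
#' flagged significant when the interval excludes 0. A Wilcoxon rank-sum
#' comparison of the before/after deviations is included as a sensitivity
#' check.
#'
#' @param dev A `deviation_series` from [compute_deviations()].
#' @param t_int_week Intervention week index (1-based within the horizon).
#' @param level CI coverage.
#' @param t_int_in_after Boundary rule (see [effect_windows()]).
#' @return `intervention_effect`: list with `delta_before`, `delta_after`,
#'   `delta`, `ci_lo`, `ci_hi`, `significant`, `t_int_week`, `windows`,
#'   `replicate_effects`, `p_wilcoxon`, `state`, `pollutant`, `level`.
#' @export
estimate_effect <- function(dev, t_int_week, level = 0.95,
                            t_int_in_after = TRUE) {
  stopifnot(inherits(dev, "deviation_series"))
  h <- length(dev$delta)
  w <- effect_windows(t_int_week, h, t_int_in_after = t_int_in_after)
  if (!length(w$before) || !length(w$after)) stop("empty effect window")
  delta_before <- median(dev$delta[w$before])
  delta_after <- median(dev$delta[w$after])
  rep_eff <- apply(dev$replicate_deltas, 1, function(d)
    median(d[w$before]) - median(d[w$after]))
  a <- (1 - level) / 2
  ci <- quantile(rep_eff, c(a, 1 - a), names = FALSE)
  pw <- tryCatch(
    suppressWarnings(stats::wilcox.test(dev$delta[w$before],
                                        dev$delta[w$after])$p.value),
    error = function(e) NA_real_)
  structure(list(delta_before = delta_before, delta_after = delta_after,
                 delta = delta_before - delta_after,
                 ci_lo = ci[1], ci_hi = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 t_int_week = as.integer(t_int_week), windows = w,
                 replicate_effects = rep_eff, p_wilcoxon = pw,
                 state = dev$state, pollutant = dev$pollutant, level = level),
            class = "intervention_effect")
}

#' @export
print.intervention_effect <- function(x, ...) {
  cat(sprintf("<intervention_effect> %s %s: delta = %.3f [%.3f, %.3f]%s (before %.3f, after %.3f; intervention week %d)\n",
              x$state, x$pollutant, x$delta, x$ci_lo, x$ci_hi,
              if (x$significant) " *" else "", x$delta_before, x$delta_after,
              x$t_int_week))
  invisible(x)
}

#' Cross-pollutant ratio of intervention effects
#'
#' `rho = delta_NO2 / delta_PM2.5`; negative values mean the two pollutants
#' moved in opposite directions, and larger magnitudes mean a larger
#' discrepancy. A zero PM2.5 effect makes the ratio undefined: an `NA`
#' marker with `defined = FALSE` is returned (with a message), never an
#' error.
#'
#' @param effect_no2,effect_pm25 `intervention_effect` objects (or bare
#'   effect numbers).
#' @return List with `rho`, `defined`, `state`.
#' @export
compute_ratio <- function(effect_no2, effect_pm25) {
  num <- if (inherits(effect_no2, "intervention_effect")) effect_no2$delta else effect_no2
  den <- if (inherits(effect_pm25, "intervention_effect")) effect_pm25$delta else effect_pm25
  state <- if (inherits(effect_no2, "intervention_effect")) effect_no2$state else NA_character_
  if (den == 0) {
    message("zero PM2.5 effect: cross-pollutant ratio undefined",
            if (!is.na(state)) paste0(" for ", state) else "")
    return(list(rho = NA_real_, defined = FALSE, state = state))
  }
  list(rho = num / den, defined = TRUE, state = state)
}

#' Average prediction error over the forecast horizon
#'
#' The signed arithmetic mean of the weekly deviations (positive and
#' negative deviations cancel); concentration units.
#'
#' @param dev A `deviation_series`, or a bare vector of deviations.
#' @return Scalar APE.
#' @export
compute_ape <- function(dev) {
  delta <- if (inherits(dev, "deviation_series")) dev$delta else dev
  mean(delta)
}

#' Mean absolute scaled error against the one-step naive forecaster
#'
#' `mean(|actual - fitted|)` scaled by the training-window mean absolute
#' one-step naive error `mean(|Y_t - Y_(t-1)|)`. Values below 1 mean the
#' model outperforms naively carrying the last observation forward. A
#' constant training series has zero naive scale: `NA` is returned as an
#' undefined-value marker.
#'
#' @param fitted One-step fitted or forecast values.
#' @param actual Actual values aligned with `fitted`.
#' @param training_actual Training series supplying the naive scale (needs
#'   >= 2 observations).
#' @return Scalar MASE (or `NA` when undefined).
#' @export
compute_mase <- function(fitted, actual, training_actual) {
  if (length(fitted) != length(actual)) stop("fitted/actual misaligned")
  if (length(training_actual) < 2) stop("need >= 2 training observations")
  scale <- mean(abs(diff(training_actual)))
  if (scale == 0) {
    message("constant training series: MASE undefined")
    return(NA_real_)
  }
  mean(abs(actual - fitted)) / scale
}

#' Tabulate per-state intervention effects
#'
#' @param effects List of `intervention_effect` objects.
#' @return Data frame matching the effects CSV schema (state, pollutant,
#'   t_int, delta_before, delta_after, delta, ci_lo, ci_hi, significant).
#' @export
effects_table <- function(effects) {
  do.call(rbind, lapply(effects, function(e)
    data.frame(state = e$state, pollutant = e$pollutant,
               t_int = e$t_int_week, delta_before = e$delta_before,
               delta_after = e$delta_after, delta = e$delta,
               ci_lo = e$ci_lo, ci_hi = e$ci_hi,
               significant = e$significant)))
}
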