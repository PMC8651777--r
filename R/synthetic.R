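#' Configuration for the synthetic state-panel generator
#'
#' Describes a panel of state-level weekly pollutant series with known ground
#' truth: trend + annual seasonality + AR noise + additive weather effects in
#' the history, and an injected post-intervention level drop of `delta_true`
#' concentration units during the forecast period. Defaults emulate the
#' full-scale study design: five years of weekly history (52-week seasonal
#' cycle) followed by a 16-week forecast period with the intervention in
#' week 9, so the before/after windows are 8 and 8 weeks. Desk-scale runs
#' pass `seasonal_period = 12` to keep seasonal ARIMA fitting fast; the
#' generator is otherwise identical.
#'
#' @param n_states Number of states in the panel.
#' @param n_years_history Years of training history (cycles of
#'   `seasonal_period` weeks).
#' @param seasonal_period Weeks per seasonal cycle (52 = annual at weekly
#'   resolution).
#' @param forecast_horizon Forecast-period length in weeks.
#' @param baseline Mean concentration level (units of the pollutant). Keep
#'   well above `delta_true`: concentrations are floored at 0, which would
#'   otherwise bias the injected shift.
#' @param trend_slope Linear trend, concentration units per week.
#' @param seasonal_amplitude Amplitude of the sinusoidal seasonal component.
#' @param ar_coefs Autoregressive coefficients of the noise process.
#' @param noise_sd Innovation standard deviation (> 0, or exactly 0 for the
#'   deterministic limit).
#' @param weather_coefs Named length-3 vector: additive effects of centered
#'   temperature, precipitation and humidity on concentration.
#' @param intervention_week 1-based week within the forecast horizon at which
#'   the level drop begins (the intervention week itself is post-period).
#' @param delta_true Injected post-intervention drop, one value per state
#'   (recycled); `NULL` draws per-state drops from U(1, 8) under the master
#'   seed, matching the recovery-study design.
#' @param master_seed Integer; all per-state streams are derived from it via
#'   [sub_seed()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_states = 20L, n_years_history = 5L,
                       seasonal_period = 52L, forecast_horizon = 16L,
                       baseline = 30, trend_slope = -0.005,
                       seasonal_amplitude = 3, ar_coefs = 0.5, noise_sd = 1,
                       weather_coefs = c(temperature = 0.08,
                                         precipitation = -0.4,
                                         humidity = 0.02),
                       intervention_week = 9L, delta_true = NULL,
                       master_seed = 42L) {
  num <- c(n_states, n_years_history, seasonal_period, forecast_horizon,
           baseline, trend_slope, seasonal_amplitude, ar_coefs, noise_sd,
           weather_coefs, intervention_week, master_seed, delta_true)
  if (!all(is.finite(num))) stop("all sim_config parameters must be finite")
  if (seasonal_period < 2) stop("seasonal_period must be >= 2")
  if (forecast_horizon < 2) stop("forecast_horizon must be >= 2")
  if (intervention_week <= 1 || intervention_week >= forecast_horizon)
    stop("intervention_week must satisfy 1 < intervention_week < forecast_horizon")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(weather_coefs) != 3) stop("weather_coefs must have length 3")
  cfg <- list(n_states = as.integer(n_states),
              n_years_history = as.integer(n_years_history),
              seasonal_period = as.integer(seasonal_period),
              forecast_horizon = as.integer(forecast_horizon),
              baseline = baseline, trend_slope = trend_slope,
              seasonal_amplitude = seasonal_amplitude, ar_coefs = ar_coefs,
              noise_sd = noise_sd,
              weather_coefs = setNames(as.numeric(weather_coefs),
                                       c("temperature", "precipitation", "humidity")),
              intervention_week = as.integer(intervention_week),
              delta_true = delta_true, master_seed = as.integer(master_seed))
  class(cfg) <- "sim_config"
  cfg
}

# per-state delta_true vector implied by a config (U(1,8) when unset)
resolve_delta_true <- function(config) {
  if (is.null(config$delta_true)) {
    with_seed(sub_seed(config$master_seed, "delta_true"),
              runif(config$n_states, 1, 8))
  } else rep_len(config$delta_true, config$n_states)
}

#' Simulate one state's weekly pollutant series with known ground truth
#'
#' Generates `n_years_history * seasonal_period` training weeks plus
#' `forecast_horizon` forecast weeks. The concentration is
#' baseline + trend + sinusoidal seasonality + weather effects (centered
#' covariates times `weather_coefs`) + AR noise; forecast weeks from
#' `intervention_week` onward are lowered by exactly `delta_true` before the
#' non-negativity floor. Weather covariates are smooth seasonal signals plus
#' noise, with state-specific phases. The state's RNG stream is derived from
#' `(master_seed, state_id)`, so states are mutually independent and each
#' call is reproducible.
#'
#' @param config A [sim_config()].
#' @param state_id Label identifying the state (also seeds its RNG stream).
#' @param delta_true Override for this state's injected drop; defaults to the
#'   value implied by the config for this state's position.
#' @param state_index Position of the state in the panel (used only to pick
#'   its `delta_true` when drawn from the config).
#' @param pollutant Label for the simulated pollutant (also varies the RNG
#'   stream, so pollutants are independent given the state).
#' @return A [weekly_series()] with attribute `ground_truth`, a list with
#'   `delta_true`, `intervention_week` and the generating coefficients.
#' @export
simulate_state_series <- function(config, state_id, delta_true = NULL,
                                  state_index = 1L, pollutant = "pm25") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(delta_true)) delta_true <- resolve_delta_true(config)[state_index]
  if (!is.finite(delta_true)) stop("delta_true must be finite")
  m <- config$seasonal_period
  n_train <- config$n_years_history * m
  h <- config$forecast_horizon
  n <- n_train + h
  t_idx <- seq_len(n)

  with_seed(sub_seed(config$master_seed, "series", state_id, pollutant), {
    ph <- runif(3, 0, 2 * pi)  # state-specific seasonal phases for weather
    w <- 2 * pi * t_idx / m
    temperature <- 15 + 10 * sin(w + ph[1]) + rnorm(n, 0, 2)
    precipitation <- pmax(0, 2 + 1.5 * sin(w + ph[2]) + rnorm(n, 0, 1))
    humidity <- 60 + 15 * sin(w + ph[3]) + rnorm(n, 0, 5)
    noise <- if (config$noise_sd > 0 || any(config$ar_coefs != 0)) {
      innov <- rnorm(n, 0, config$noise_sd)
      as.numeric(stats::filter(innov, config$ar_coefs, method = "recursive"))
    } else rep(0, n)
  })

  X <- cbind(temperature = temperature, precipitation = precipitation,
             humidity = humidity)
  Xc <- sweep(X, 2, colMeans(X[seq_len(n_train), , drop = FALSE]))
  mu <- config$baseline + config$trend_slope * t_idx +
    config$seasonal_amplitude * sin(2 * pi * t_idx / m) +
    as.numeric(Xc %*% config$weather_coefs)
  y <- mu + noise
  post <- t_idx > n_train + (config$intervention_week - 1L)
  y[post] <- y[post] - delta_true
  y <- pmax(y, 0)

  anchor <- as.Date("2020-01-01")
  ws <- weekly_series(week_start = anchor + 7 * (t_idx - n_train - 1L),
                      value = y, temperature = temperature,
                      precipitation = precipitation, humidity = humidity,
                      split_index = n_train, state = state_id,
                      pollutant = pollutant)
  attr(ws, "period") <- m
  attr(ws, "ground_truth") <- list(delta_true = delta_true,
                                   intervention_week = config$intervention_week,
                                   weather_coefs = config$weather_coefs,
                                   baseline = config$baseline,
                                   ar_coefs = config$ar_coefs)
  ws
}

#' Simulate a panel of states plus ground truth and intervention calendar
#'
#' @param config A [sim_config()].
#' @param pollutant Pollutant label for all series in the panel.
#' @return List with `series` (named list of [weekly_series()]), `truth`
#'   (data frame: state, delta_true, intervention_week) and `calendar`
#'   (data frame: state, emergency_date — mid-week of the intervention week,
#'   so [week_index_of()] recovers `intervention_week`).
#' @export
simulate_panel <- function(config, pollutant = "pm25") {
  stopifnot(inherits(config, "sim_config"))
  states <- sprintf("S%02d", seq_len(config$n_states))
  deltas <- resolve_delta_true(config)
  series <- lapply(seq_along(states), function(i)
    simulate_state_series(config, states[i], delta_true = deltas[i],
                          pollutant = pollutant))
  names(series) <- states
  anchor <- as.Date("2020-01-01")
  list(series = series,
       truth = data.frame(state = states, delta_true = deltas,
                          intervention_week = config$intervention_week),
       calendar = data.frame(state = states,
                             emergency_date = anchor +
                               7 * (config$intervention_week - 1L) + 3))
}

#' Simulate state covariates and intervention-effect outcomes for the
#' heterogeneity regression
#'
#' Emissions-source shares (fire, stationary, mobile, biogenic) are drawn on
#' the simplex from a Dirichlet distribution and the biogenic share is then
#' dropped, so the three retained proportions do not sum to 1. Population
#' density is log-normal; Census regions are assigned in balanced rotation.
#' Outcomes are generated from the same centered main-effects +
#' all-two-factor-interactions design that [fit_wmlr()] fits, with
#' heteroscedastic normal noise whose per-state SD is drawn uniformly from
#' `het_sd_range`; the true SDs are returned so tests can build
#' inverse-variance weights.
#'
#' @param n_states Number of states (must exceed the number of regression
#'   parameters).
#' @param regression_coefs Named numeric vector of true coefficients; names
#'   must match columns of the design built by [build_design()] (see its
#'   return value); unnamed columns get coefficient 0.
#' @param het_sd_range Length-2 range for the per-state noise SD.
#' @param seed Integer seed for this draw.
#' @return List: `covariates` (data frame state, prop_fire, prop_stationary,
#'   prop_mobile, population_density, region), `delta` (outcome vector),
#'   `sd_true`, `coefs` (full coefficient vector on design columns),
#'   `proportions_full` (all four source shares, rows summing to 1).
#' @export
simulate_state_covariates <- function(n_states = 40L,
                                      regression_coefs = c(`(Intercept)` = 2,
                                                           prop_mobile = 8,
                                                           prop_stationary = -4,
                                                           log_density = 0.8,
                                                           `prop_mobile:log_density` = 3),
                                      het_sd_range = c(0.2, 1.5),
                                      seed = 1L) {
  stopifnot(length(het_sd_range) == 2, all(het_sd_range >= 0))
  covariates <- with_seed(sub_seed(seed, "covariates"), {
    alpha <- c(fire = 1.2, stationary = 4, mobile = 4, biogenic = 2)
    g <- matrix(rgamma(n_states * 4, shape = rep(alpha, each = n_states)),
                nrow = n_states)
    props <- g / rowSums(g)
    colnames(props) <- names(alpha)
    regions <- sample(rep_len(c("Northeast", "Midwest", "South", "West"),
                              n_states))
    data.frame(state = sprintf("S%02d", seq_len(n_states)),
               prop_fire = props[, "fire"],
               prop_stationary = props[, "stationary"],
               prop_mobile = props[, "mobile"],
               population_density = exp(rnorm(n_states, 4, 1)),
               region = regions, proportions_full = I(props))
  })
  props_full <- unclass(covariates$proportions_full)
  covariates$proportions_full <- NULL

  design <- build_design(covariates)
  X <- design$X
  if (n_states <= ncol(X))
    stop(sprintf("need more states (%d) than regression parameters (%d)",
                 n_states, ncol(X)))
  beta <- setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(regression_coefs), names(beta))
  if (length(unknown))
    stop("regression_coefs name columns absent from the design: ",
         paste(unknown, collapse = ", "))
  beta[names(regression_coefs)] <- regression_coefs

  out <- with_seed(sub_seed(seed, "outcomes"), {
    sd_true <- runif(n_states, het_sd_range[1], het_sd_range[2])
    list(sd_true = sd_true,
         delta = as.numeric(X %*% beta) + rnorm(n_states, 0, sd_true))
  })
  list(covariates = covariates, delta = out$delta, sd_true = out$sd_true,
       coefs = beta, proportions_full = props_full)
}
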