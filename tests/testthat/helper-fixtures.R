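# Fixtures built in code; all randomness is seeded per test.

# desk-scale simulation config: 12-week "annual" cycle keeps SARIMA fast
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(n_states = 2L, n_years_history = 5L, seasonal_period = 12L,
                   forecast_horizon = 16L, baseline = 30, trend_slope = 0,
                   seasonal_amplitude = 3, ar_coefs = 0.5, noise_sd = 1,
                   intervention_week = 9L, master_seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# deviation_series with given bagged deltas and replicate deltas
make_deviations <- function(delta, replicate_deltas = NULL) {
  if (is.null(replicate_deltas))
    replicate_deltas <- matrix(delta, nrow = 5, ncol = length(delta),
                               byrow = TRUE)
  structure(list(delta = delta, replicate_deltas = replicate_deltas,
                 week_start = seq_along(delta), state = "ZZ",
                 pollutant = "pm25"),
            class = "deviation_series")
}

# daily records for one state/pollutant: value[i] on day dates[i]
daily_records <- function(dates, values, state = "AA", pollutant = "pm25") {
  data.frame(date = as.Date(dates), state = state, pollutant = pollutant,
             value = values)
}

# constant daily weather covering a date span
flat_weather <- function(from, to, state = "AA", temperature = 10,
                         precipitation = 1, humidity = 50) {
  d <- seq(as.Date(from), as.Date(to), by = "day")
  data.frame(date = d, state = state, temperature = temperature,
             precipitation = precipitation, humidity = humidity)
}

# simulate a SARIMA(1,0,0)(0,1,1)_m process with mean level
simulate_sarima_101 <- function(n, m = 12, phi = 0.5, Theta = -0.5,
                                level = 20, burn = 6 * m) {
  N <- n + burn
  eps <- rnorm(N)
  v <- eps + c(rep(0, m), Theta * eps[seq_len(N - m)])
  u <- as.numeric(stats::filter(v, phi, method = "recursive"))
  x <- numeric(N)
  x[seq_len(m)] <- u[seq_len(m)]
  for (t in (m + 1):N) x[t] <- x[t - m] + u[t]
  level + x[(burn + 1):N]
}
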