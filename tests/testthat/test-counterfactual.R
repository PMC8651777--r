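test_that("differencing choice separates stationary from seasonal-unit-root series", {
  picks <- t(vapply(1:50, function(r) {
    set.seed(4000 + r)
    y_sarima <- simulate_sarima_101(300, m = 12, phi = 0.5, Theta = -0.5)
    y_wn <- rnorm(300, 10)
    c(unlist(choose_differencing(y_sarima, 12)),
      unlist(choose_differencing(y_wn, 12)))
  }, numeric(4)))
  # modal choice for the seasonal-unit-root process: d = 0, D = 1
  expect_equal(as.integer(names(which.max(table(picks[, 1])))), 0L)
  expect_equal(as.integer(names(which.max(table(picks[, 2])))), 1L)
  # white noise needs no differencing at all
  expect_gte(mean(picks[, 3] == 0 & picks[, 4] == 0), 0.9)
})

test_that("AICc search is parsimonious on white noise and deterministic", {
  hits <- vapply(1:25, function(r) {
    set.seed(500 + r)
    spec <- select_order(rnorm(200, 50, 2), m = 12, max_p = 2, max_q = 2)
    sum(spec$order[c("p", "q")]) + sum(spec$seasonal[c("P", "Q")])
  }, numeric(1))
  expect_gte(mean(hits <= 1), 0.8)

  set.seed(501)
  y <- rnorm(150, 10)
  s1 <- select_order(y, m = 12, max_p = 2, max_q = 2)
  s2 <- select_order(y, m = 12, max_p = 2, max_q = 2)
  expect_identical(s1$order, s2$order)
  expect_identical(s1$seasonal, s2$seasonal)
  expect_equal(s1$aicc, s2$aicc)
})

test_that("constant series with zero covariate effect forecasts itself", {
  spec <- structure(list(order = c(p = 0L, d = 0L, q = 0L),
                         seasonal = c(P = 0L, D = 0L, Q = 0L),
                         period = 1L, include_mean = TRUE),
                    class = "sarima_spec")
  fc <- fit_and_forecast(rep(7, 60), NULL, NULL, spec, horizon = 16,
                         method = "CSS-ML")
  expect_equal(fc, rep(7, 16), tolerance = 1e-6)
})

test_that("AR(1) forecasts decay monotonically toward the series mean", {
  set.seed(61)
  y <- 10 + as.numeric(stats::filter(rnorm(300), 0.8, method = "recursive"))
  y[300] <- max(y) + 3  # last value far above the mean
  spec <- structure(list(order = c(p = 1L, d = 0L, q = 0L),
                         seasonal = c(P = 0L, D = 0L, Q = 0L),
                         period = 1L, include_mean = TRUE),
                    class = "sarima_spec")
  fc <- fit_and_forecast(y, NULL, NULL, spec, horizon = 12, method = "CSS-ML")
  expect_true(all(diff(fc) < 0))           # monotone decay from above
  expect_gt(fc[12], mean(y) - 1)           # toward, not past, the mean
})

test_that("fitted SARIMA recovers a known weather effect", {
  hits <- vapply(1:100, function(r) {
    # seasonal amplitude 0: the AR(1)+weather model is then correctly
    # specified, isolating the covariate-recovery property; 10 years of
    # history keeps the standard-error estimate well behaved
    cfg <- desk_config(weather_coefs = c(0.5, 0, 0), ar_coefs = 0.5,
                       seasonal_amplitude = 0, n_years_history = 10L,
                       noise_sd = 1, master_seed = 9000 + r, delta_true = 0)
    s <- simulate_state_series(cfg, "S01")
    sp <- bagsarima:::series_split(s)
    spec <- structure(list(order = c(p = 1L, d = 0L, q = 0L),
                           seasonal = c(P = 0L, D = 0L, Q = 0L),
                           period = 12L, include_mean = TRUE),
                      class = "sarima_spec")
    f <- sarima_fitted(sp$y_train, sp$xreg_train, spec)
    if (is.null(f)) return(NA)
    est <- coef(f$fit)["temperature"]
    se <- sqrt(diag(f$fit$var.coef))["temperature"]
    abs(est - 0.5) <= 2 * se
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("psi weights match the AR(1) closed form and the forecast SEs", {
  set.seed(91)
  y <- 10 + as.numeric(stats::filter(rnorm(400), 0.7, method = "recursive"))
  fit <- arima(y, order = c(1, 0, 0))
  phi <- unname(coef(fit)["ar1"])
  psi <- psi_weights(fit, 8)
  expect_equal(psi, phi^(0:7), tolerance = 1e-10)  # AR(1): psi_j = phi^j
  # sigma * sqrt(cumsum(psi^2)) reproduces predict()'s forecast SEs
  se_psi <- sqrt(fit$sigma2 * cumsum(psi^2))
  expect_equal(se_psi, as.numeric(predict(fit, n.ahead = 8)$se),
               tolerance = 1e-6)

  # seasonal model: the identity still holds through the polynomial expansion
  set.seed(92)
  ys <- simulate_sarima_101(300, m = 12, phi = 0.5, Theta = -0.5)
  fs <- arima(ys, order = c(1, 0, 0),
              seasonal = list(order = c(0, 1, 1), period = 12))
  ses <- sqrt(fs$sigma2 * cumsum(psi_weights(fs, 16)^2))
  expect_equal(ses, as.numeric(predict(fs, n.ahead = 16)$se),
               tolerance = 1e-6)
})

test_that("simulated future-innovation paths have the model's forecast variance", {
  set.seed(93)
  y <- 10 + as.numeric(stats::filter(rnorm(400), 0.7, method = "recursive"))
  fit <- arima(y, order = c(1, 0, 0))
  errs <- replicate(3000, bagsarima:::simulate_forecast_error(fit, 6))
  se_mc <- apply(errs, 1, sd)
  se_th <- as.numeric(predict(fit, n.ahead = 6)$se)
  expect_equal(se_mc, se_th, tolerance = 0.08)
  expect_lt(max(abs(rowMeans(errs))), 4 * max(se_th) / sqrt(3000))
})

test_that("bagging averages replicate paths and collapses degenerate bands", {
  path <- sin(1:16) + 5
  same <- matrix(path, nrow = 12, ncol = 16, byrow = TRUE)
  cf <- bag_forecasts(same, observed = rep(5, 16))
  expect_equal(cf$c_pred, path)
  expect_equal(cf$lo, path)
  expect_equal(cf$hi, path)

  two <- rbind(rep(0, 4), rep(2, 4))
  expect_equal(bag_forecasts(two, rep(1, 4))$c_pred, rep(1, 4))

  holes <- rbind(matrix(1, 3, 4), matrix(NA_real_, 4, 4))
  expect_error(bag_forecasts(holes, rep(1, 4)), "converged")
  expect_error(bag_forecasts(matrix(1, 4, 3), rep(1, 4)), "misaligned")
})

test_that("bagged mean stays inside its own percentile band", {
  set.seed(71)
  paths <- matrix(rnorm(200 * 16, 10), 200, 16)
  cf <- bag_forecasts(paths, rnorm(16, 10))
  expect_true(all(cf$c_pred >= cf$lo & cf$c_pred <= cf$hi))
})

test_that("95% bands cover no-intervention observations most weeks", {
  cover <- vapply(1:10, function(r) {
    cfg <- desk_config(delta_true = 0, master_seed = 1200 + r)
    s <- simulate_state_series(cfg, "S01")
    cf <- counterfactual_forecast(s, B = 50, seed = 1300 + r,
                                  max_p = 2, max_q = 2)
    mean(cf$c_obs >= cf$lo & cf$c_obs <= cf$hi)
  }, numeric(1))
  expect_gte(mean(cover), 0.85)
})

test_that("counterfactual machinery never consumes the intervention date", {
  cfg <- desk_config(delta_true = 5, master_seed = 88)
  pan <- simulate_panel(cfg)
  s <- pan$series[[1]]
  cal <- intervention_calendar(pan$calendar)

  plain <- counterfactual_forecast(s, B = 30, seed = 7, max_p = 2, max_q = 2)
  t_int <- week_index_of(cal, s, attr(s, "state"))
  with_cal <- run_state_analysis(s, t_int_week = t_int, B = 30, seed = 7,
                                 max_p = 2, max_q = 2)
  expect_identical(plain$c_pred, with_cal$forecast$c_pred)
  expect_identical(plain$paths, with_cal$forecast$paths)
})

test_that("validation run holds out the final training year without leakage", {
  cfg <- desk_config(delta_true = 6, master_seed = 99)
  s <- simulate_state_series(cfg, "S01")
  v <- validation_run(s, B = 25, seed = 3, max_p = 2, max_q = 2)
  split <- attr(s, "split_index")
  h <- forecast_horizon(s)
  expect_length(v$c_pred, h)
  # validation observations are the held-out end of the training window
  expect_equal(v$c_obs, s$value[(split - h + 1):split])

  # poisoning the discarded forecast period cannot change the result
  poisoned <- s
  poisoned$value[(split + 1):nrow(s)] <- 1e6
  v2 <- validation_run(poisoned, B = 25, seed = 3, max_p = 2, max_q = 2)
  expect_identical(v$c_pred, v2$c_pred)

  # deviations of a no-intervention hold-out center near zero
  expect_lt(abs(median(v$c_obs - v$c_pred)), 1.5)
})

test_that("per-state pipeline recovers an injected decline", {
  runs <- lapply(1:5, function(r) {
    cfg <- desk_config(delta_true = 5, master_seed = 40 + r)
    s <- simulate_state_series(cfg, "S01")
    run_state_analysis(s, t_int_week = 9, B = 50, seed = r,
                       max_p = 2, max_q = 2)
  })
  deltas <- vapply(runs, function(r) r$effect$delta, numeric(1))
  after_med <- vapply(runs, function(r) median(r$deviations$delta[9:16]),
                      numeric(1))
  before_med <- vapply(runs, function(r) median(r$deviations$delta[1:8]),
                       numeric(1))
  expect_lt(abs(mean(deltas) - 5), 1)
  expect_lt(abs(mean(after_med) + 5), 1)   # after weeks sit near -delta_true
  expect_lt(abs(mean(before_med)), 1)      # pre-intervention median near zero
  mases <- vapply(runs, function(r) r$assessment$mase, numeric(1))
  expect_true(all(is.finite(mases)))
  expect_lt(median(mases), 1)
})
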