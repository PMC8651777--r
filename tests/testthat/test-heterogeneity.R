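make_cov_table <- function(n = 40, seed = 3, regions = c("Northeast",
                                                         "Midwest", "South",
                                                         "West")) {
  set.seed(seed)
  g <- matrix(rgamma(n * 4, 2), n, 4)
  p <- g / rowSums(g)
  data.frame(state = sprintf("S%02d", 1:n), prop_fire = p[, 1],
             prop_stationary = p[, 2], prop_mobile = p[, 3],
             population_density = exp(rnorm(n, 4, 1)),
             region = sample(rep_len(regions, n)))
}

test_that("design has mains plus all two-factor interactions", {
  d <- build_design(make_cov_table(40))
  # intercept + 4 continuous + 3 region dummies + C(4,2) cont x cont
  # + 4 x 3 cont x region = 1 + 7 + 6 + 12 = 26 columns
  expect_equal(ncol(d$X), 26L)
  expect_equal(sum(grepl(":", colnames(d$X))), 18L)
  expect_equal(qr(d$X)$rank, 26L)
  expect_length(d$dropped, 0L)
  # mains-only sensitivity design
  expect_equal(ncol(build_design(make_cov_table(40), interactions = FALSE)$X), 8L)
})

test_that("degenerate factors and duplicated predictors are handled", {
  one_region <- make_cov_table(30, regions = "South")
  expect_warning(d <- build_design(one_region), "single level")
  expect_equal(ncol(d$X), 1L + 4L + 6L)
  expect_false(any(grepl("region", colnames(d$X))))

  dup <- make_cov_table(40)
  dup$population_density <- exp(dup$prop_fire)  # log-density duplicates a column
  expect_message(d2 <- build_design(dup), "rank-deficient")
  expect_gt(length(d2$dropped), 0L)
  expect_equal(qr(d2$X)$rank, ncol(d2$X))

  bad <- make_cov_table(40); bad$prop_fire <- bad$prop_fire + 1
  expect_error(build_design(bad), "proportions")
  expect_error(build_design(make_cov_table(20)), "more parameters")
})

test_that("equal weights reproduce OLS; weight scaling leaves estimates unchanged", {
  tab <- make_cov_table(40)
  set.seed(8)
  y <- rnorm(40, 1)
  d <- build_design(tab)
  f <- fit_wmlr(d, y)
  ols <- lm.fit(d$X, y)
  expect_equal(unname(f$coefficients$estimate), unname(ols$coefficients),
               tolerance = 1e-8)

  w <- runif(40, 0.5, 4)
  a <- fit_wmlr(d, y, weights = w)
  b <- fit_wmlr(d, y, weights = w * 137.5)
  expect_equal(a$coefficients$estimate, b$coefficients$estimate)
  expect_equal(a$coefficients$se, b$coefficients$se)
  expect_equal(a$r2, b$r2)
})

test_that("noise-free outcomes are interpolated exactly", {
  sim <- simulate_state_covariates(n_states = 40, het_sd_range = c(0, 0),
                                   seed = 12)
  f <- fit_wmlr(sim$covariates, sim$delta)
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(est[names(sim$coefs)], sim$coefs, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("inverse-variance weighting beats OLS under heteroscedasticity", {
  errs <- vapply(1:200, function(r) {
    sim <- simulate_state_covariates(n_states = 40, seed = 3000 + r,
                                     het_sd_range = c(0.2, 2.5))
    d <- build_design(sim$covariates)
    fw <- fit_wmlr(d, sim$delta, weights = 1 / sim$sd_true^2)
    fo <- fit_wmlr(d, sim$delta)
    nz <- names(sim$coefs)[sim$coefs != 0]
    idx <- match(nz, fw$coefficients$term)
    c(sqrt(mean((fw$coefficients$estimate[idx] - sim$coefs[nz])^2)),
      sqrt(mean((fo$coefficients$estimate[idx] - sim$coefs[nz])^2)))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("interaction model fits interaction-generated data better (adj R2)", {
  sim <- simulate_state_covariates(
    n_states = 44, seed = 21,
    regression_coefs = c(`(Intercept)` = 1, prop_mobile = 6,
                         prop_stationary = -3, log_density = 0.5,
                         `prop_mobile:log_density` = 4,
                         `prop_fire:prop_mobile` = 25),
    het_sd_range = c(0.3, 0.8))
  w <- 1 / sim$sd_true^2
  full <- fit_wmlr(build_design(sim$covariates), sim$delta, weights = w)
  mains <- fit_wmlr(build_design(sim$covariates, interactions = FALSE),
                    sim$delta, weights = w)
  expect_gt(full$adj_r2, mains$adj_r2)
})
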