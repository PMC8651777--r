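test_that("Box-Cox closed forms and round trip", {
  expect_equal(boxcox_transform(c(1, exp(1), exp(2)), lambda = 0)$y, c(0, 1, 2))
  x <- c(2, 5, 9)
  expect_equal(boxcox_transform(x, lambda = 1)$y, x - 1)
  set.seed(11)
  for (lam in c(0, 0.3, 0.77, 1)) {
    x <- exp(rnorm(200, 2, 0.7))
    bc <- boxcox_transform(x, lambda = lam)
    back <- boxcox_inverse(bc$y, bc$lambda, bc$offset)
    expect_lt(max(abs(back - x) / x), 1e-10)
  }
})

test_that("Box-Cox offsets zero-containing series and rejects negatives", {
  x <- c(0, 2, 4, 8)
  bc <- boxcox_transform(x, lambda = 0.5)
  expect_equal(bc$offset, 1)  # half the smallest positive value
  expect_true(all(is.finite(bc$y)))
  expect_equal(boxcox_inverse(bc$y, bc$lambda, bc$offset), x)
  expect_error(boxcox_transform(c(-1, 2), lambda = 1), "negative")
})

test_that("estimated lambda lies in [0, 1] and stabilizes multiplicative noise", {
  set.seed(21)
  t_idx <- 1:120
  mult <- exp(0.3 * sin(2 * pi * t_idx / 12)) * exp(rnorm(120, 3, 0.1))
  lam <- boxcox_transform(mult, period = 12)$lambda
  expect_gte(lam, 0); expect_lte(lam, 1)
  expect_lt(lam, 0.5)  # log-like transform for a multiplicative series
})

test_that("STL decomposition: additive identity, sine recovery, constants", {
  t_idx <- 1:144
  sine <- sin(2 * pi * t_idx / 12)
  dec <- stl_decompose(10 + sine, 12)
  expect_gt(cor(dec$seasonal, sine), 0.99)
  expect_true(all(abs(dec$trend - 10) < 0.2))
  expect_lt(max(abs(dec$remainder)), 0.2)
  expect_equal(dec$trend + dec$seasonal + dec$remainder, 10 + sine,
               tolerance = 1e-8)

  const <- stl_decompose(rep(5, 48), 12)
  expect_lt(max(abs(const$seasonal)), 1e-8)
  expect_true(all(abs(const$trend - 5) < 1e-8))

  set.seed(3)
  y <- 10 + sine + rnorm(144, 0, 0.5)
  dec2 <- stl_decompose(y, 12)
  expect_equal(dec2$trend + dec2$seasonal + dec2$remainder, y,
               tolerance = 1e-8)
  expect_error(stl_decompose(rnorm(20), 12), "below 2 x period")
})

test_that("moving-block bootstrap: degenerate block, closure, range errors", {
  set.seed(41)
  r <- rnorm(30)
  expect_identical(moving_block_resample(r, 30), r)
  rs <- moving_block_resample(r, 7)
  expect_length(rs, 30)
  expect_true(all(rs %in% r))  # no new values invented
  expect_error(moving_block_resample(r, 0), "block_length")
  expect_error(moving_block_resample(r, 31), "block_length")
})

test_that("block length 1 reproduces the i.i.d. bootstrap mean", {
  set.seed(42)
  r <- rnorm(50, 2, 1)
  draws <- replicate(2000, mean(moving_block_resample(r, 1)))
  # grand mean of 2000 i.i.d.-bootstrap means: SE = sd(r) / sqrt(50 * 2000)
  expect_lt(abs(mean(draws) - mean(r)), 3 * sd(r) / sqrt(50 * 2000))
  # and each draw only permutes observed values
  expect_true(all(draws >= min(r) & draws <= max(r)))
})

test_that("ensemble degenerate cases and determinism", {
  set.seed(5)
  t_idx <- 1:72
  x <- 20 + 4 * sin(2 * pi * t_idx / 12)
  one <- generate_ensemble(x, B = 1, period = 12, block_length = 72, seed = 9)
  expect_equal(one$replicates[1, ], x)  # replicate 1 reserved as original

  # noise-free seasonal fixture: remainder ~ 0, replicates ~ original
  ens <- generate_ensemble(x, B = 20, period = 12, block_length = 24, seed = 9)
  expect_lt(max(abs(sweep(ens$replicates, 2, x))), 0.05)

  y <- x + rnorm(72, 0, 1.5)
  a <- generate_ensemble(y, B = 15, period = 12, seed = 33)
  b <- generate_ensemble(y, B = 15, period = 12, seed = 33)
  expect_identical(a$replicates, b$replicates)
  c3 <- generate_ensemble(y, B = 15, period = 12, seed = 34)
  expect_false(identical(a$replicates[2, ], c3$replicates[2, ]))
})

test_that("replicates of a strictly positive series stay strictly positive", {
  set.seed(6)
  t_idx <- 1:96
  y <- pmax(0.05, 2 + 1.5 * sin(2 * pi * t_idx / 12) + rnorm(96, 0, 0.8))
  ens <- generate_ensemble(y, B = 40, period = 12, seed = 2)
  expect_true(all(ens$replicates > 0))
  expect_equal(nrow(ens$replicates), 40L)
  expect_equal(ncol(ens$replicates), 96L)
})

test_that("ensemble mean is centered on the original series", {
  set.seed(77)
  t_idx <- 1:120
  y <- 15 + 3 * sin(2 * pi * t_idx / 12) +
    as.numeric(stats::filter(rnorm(120, 0, 1), 0.5, method = "recursive"))
  y <- pmax(y, 0.1)
  ens <- generate_ensemble(y, B = 500, period = 12, block_length = 24,
                           seed = 8, include_original = FALSE)
  # the replicate distribution brackets the original pointwise: each week's
  # observed value within 2 replicate SDs of the ensemble mean ~95% of weeks
  spread <- apply(ens$replicates, 2, sd)
  ok <- abs(colMeans(ens$replicates) - y) <= 2 * spread
  expect_gte(mean(ok), 0.9)
  # and the bagged mean tracks the deseasonalized level: grand means agree
  expect_lt(abs(mean(ens$replicates) - mean(y)), 2 * mean(spread) / sqrt(120))
})
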