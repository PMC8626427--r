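test_that("noiseless linear inputs are recovered at machine precision", {
  years <- 1988:2019
  s <- data.frame(fire_year = years, value = 2 * (years - 1988) + 1)
  f <- fit_linear(s)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_lt(f$p_value, 1e-10)
  expect_equal(f$predict(2000), 25, tolerance = 1e-9)

  const <- data.frame(fire_year = years, value = rep(5, length(years)))
  fc <- fit_linear(const)
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$p_value, 1)

  expect_error(fit_linear(s[1:2, ]), "at least 3")
})

test_that("noiseless exponential inputs recover the growth rate exactly", {
  years <- 1988:2019
  s <- data.frame(fire_year = years, value = 100 * 1.14^(years - 1988))
  f <- fit_exponential(s)
  expect_equal(f$growth_rate, 0.14, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  const <- data.frame(fire_year = years, value = rep(3, 32))
  expect_equal(fit_exponential(const)$growth_rate, 0, tolerance = 1e-12)

  # scale equivariance: rescaling the series leaves the rate unchanged
  s2 <- transform(s, value = value * 1e6)
  expect_equal(fit_exponential(s2)$growth_rate, f$growth_rate,
               tolerance = 1e-12)

  # zeros are excluded with a message, then the fit proceeds
  sz <- s; sz$value[5] <- 0
  expect_message(fz <- fit_exponential(sz), "excluding 1")
  expect_equal(fz$n, 31)
  expect_equal(fz$n_excluded, 1)
})

test_that("slope test attains its nominal type-I error under the null", {
  set.seed(2024)
  n_rep <- 2000
  rej <- 0L
  for (r in seq_len(n_rep)) {
    s <- data.frame(fire_year = 1:20, value = rnorm(20))
    if (fit_linear(s)$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("percent change between halves follows the mean-ratio definition", {
  s <- data.frame(fire_year = 1988:1991, value = c(2, 2, 9, 9))
  expect_equal(percent_change_halves(s, 1990), 350)
  expect_equal(percent_change_halves(
    data.frame(fire_year = 1:4, value = c(3, 3, 3, 3)), 3), 0)
  # a five-fold increase reads as +500%
  expect_equal(percent_change_halves(
    data.frame(fire_year = 1:2, value = c(1, 6)), 2), 500)
  expect_error(percent_change_halves(s, 1988), "both halves")
  expect_error(percent_change_halves(
    data.frame(fire_year = 1:2, value = c(0, 1)), 2), "positive")
})

test_that("burned-area vs FFDI-days fit recovers a known per-day multiplier", {
  years <- 1988:2018
  days <- data.frame(fire_year = years, days = seq(8, 38, length.out = 31))
  area <- data.frame(fire_year = years, area_km2 = 50 * 1.21^days$days)
  f <- fit_burned_vs_ffdi(area, days)
  expect_equal(f$multiplier_per_day, 1.21, tolerance = 1e-12)
  expect_equal(f$percent_per_day, 21, tolerance = 1e-9)

  dconst <- data.frame(fire_year = years, days = rep(10, 31))
  expect_error(fit_burned_vs_ffdi(area, dconst), "constant")
  expect_error(fit_burned_vs_ffdi(area[1:10, ], days), "different fire years")
})

test_that("multivariate fit decomposes variance sequentially and flags collinearity", {
  set.seed(7)
  years <- 1988:2018
  ffdi_days <- runif(31, 5, 40)
  # response generated from the first predictor only
  area <- data.frame(fire_year = years,
                     area_km2 = exp(1 + 0.1 * ffdi_days + rnorm(31, 0, 0.1)))
  noise1 <- data.frame(fire_year = years, value = rnorm(31))
  noise2 <- data.frame(fire_year = years, value = rnorm(31))
  fit <- fit_multivariate(area, list(
    ffdi25 = data.frame(fire_year = years, value = ffdi_days),
    chaines = noise1, dry_lightning = noise2))
  expect_gt(fit$r2_first, 0.9)
  expect_true(all(fit$delta_r2 < 0.08))
  expect_true(all(fit$delta_r2 >= -1e-12))   # R^2 never decreases
  expect_equal(fit$r2_full, fit$r2_first + sum(fit$delta_r2),
               tolerance = 1e-12)

  # orthogonal predictors with constructed variance shares
  x1 <- rep(c(-1, 1), length.out = 31) * 2
  x2 <- rep(c(-1, -1, 1, 1), length.out = 31) * 2
  area2 <- data.frame(fire_year = years, area_km2 = exp(x1 + x2))
  fit2 <- fit_multivariate(area2, list(
    a = data.frame(fire_year = years, value = x1),
    b = data.frame(fire_year = years, value = x2)))
  expect_equal(fit2$r2_full, 1, tolerance = 1e-9)
  expect_gt(fit2$delta_r2[["b"]], 0.2)

  # duplicated predictor columns: rank-deficiency error naming the column
  dup <- data.frame(fire_year = years, value = ffdi_days)
  expect_error(fit_multivariate(area, list(ffdi25 = dup, copy = dup)),
               "collinear")
})

test_that("held-out prediction is exp of the linear predictor with an extrapolation guard", {
  years <- 1988:2018
  days <- data.frame(fire_year = years, days = seq(8, 38, length.out = 31))
  set.seed(11)
  area <- data.frame(fire_year = years,
                     area_km2 = 50 * 1.19^days$days * exp(rnorm(31, 0, 0.2)))
  f <- fit_burned_vs_ffdi(area, days)
  x <- 30
  expect_equal(predict_held_out(f, x),
               exp(f$intercept + f$slope * x), tolerance = 1e-12)
  # at the predictor mean the prediction is the geometric mean of the fits
  xm <- mean(days$days)
  expect_equal(predict_held_out(f, xm),
               exp(mean(log(f$fitted))), tolerance = 1e-9)
  expect_warning(predict_held_out(f, 60), "extrapolating")
  expect_silent(predict_held_out(f, 20))
})
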