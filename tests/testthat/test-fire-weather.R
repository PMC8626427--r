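test_that("KBDI saturates at its clamps and matches the closed-form ET step", {
  # heavy rain drives the index to 0
  wet <- kbdi_update(150, 300, 20, 800)
  expect_lt(wet$kbdi, 1)
  # sustained heavy rain: index falls to its wet steady state (the daily
  # ET increment keeps it marginally above the hard floor)
  long_wet <- kbdi_series(rep(100, 30), rep(15, 30), 800, kbdi0 = 200)
  expect_lt(long_wet[30], 1)

  # prolonged hot drought drives it to the 203.2 mm cap
  dry <- kbdi_series(rep(0, 2000), rep(40, 2000), 300, kbdi0 = 0)
  expect_equal(dry[2000], 203.2, tolerance = 1e-6)
  expect_true(all(dry <= 203.2 + 1e-9 & dry >= 0))

  # one dry step from KBDI = 100: increment equals the published ET term,
  # written out independently here
  q <- 100; tmax <- 30; ra <- 700
  et <- (203.2 - q) * (0.968 * exp(0.0875 * tmax + 1.5552) - 8.3) /
    (1 + 10.88 * exp(-0.001736 * ra)) * 1e-3
  step <- kbdi_update(q, 0, tmax, ra)
  expect_equal(step$kbdi, q + et, tolerance = 1e-12)

  expect_error(kbdi_update(100, -1, 20, 800), "non-negative")
  expect_error(kbdi_update(250, 0, 20, 800), "203.2")
})

test_that("the 5.08 mm interception allowance is shared across a rain event", {
  # day 1: 4 mm (all intercepted), day 2: 4 mm (only 1.08 intercepted)
  d1 <- kbdi_update(100, 4, 10, 800)
  expect_equal(d1$kbdi, kbdi_update(100, 0, 10, 800)$kbdi, tolerance = 1e-9)
  d2 <- kbdi_update(d1$kbdi, 4, 10, 800, carry_prev = d1$carry)
  d2_naive <- kbdi_update(d1$kbdi, 4, 10, 800, carry_prev = 0)
  expect_lt(d2$kbdi, d2_naive$kbdi)  # carried interception frees more rain
  # a dry day resets the allowance
  d3 <- kbdi_update(100, 0, 10, 800, carry_prev = 5.08)
  expect_equal(d3$carry, 0)
})

test_that("KBDI stays within [0, 203.2] on adversarial rain/heat sequences", {
  set.seed(77)
  rain <- rexp(3000, 1 / 3) * rbinom(3000, 1, 0.3)
  rain[sample(3000, 20)] <- 500             # deluges
  tmax <- runif(3000, -10, 55)              # heat extremes
  kb <- kbdi_series(rain, tmax, 100, kbdi0 = 100)
  expect_true(all(kb >= 0 & kb <= 203.2 + 1e-9))
  kb2 <- kbdi_series(rain, tmax, 4000, kbdi0 = 203.2)
  expect_true(all(kb2 >= 0 & kb2 <= 203.2 + 1e-9))
})

test_that("drought factor is capped, near zero after rain, and matches its closed form", {
  # long drought at maximal KBDI: the cap
  expect_equal(drought_factor(203.2, 365, 0), 10)
  # immediately after a large rain event: small
  expect_lt(drought_factor(100, 0, 80), 0.5)
  # mid-range case against a brute-force evaluation of the adopted form
  kbdi <- 120; N <- 7; P <- 12
  x <- N^1.3 / (N^1.3 + P - 2)
  df_expected <- 10.5 * (1 - exp(-(kbdi + 30) / 40)) *
    (41 * x^2 + x) / (40 * x^2 + x + 1)
  expect_equal(drought_factor(kbdi, N, P), min(df_expected, 10),
               tolerance = 1e-12)
  # monotone in KBDI and in days since rain
  expect_true(all(diff(drought_factor(seq(0, 203, 1), 10, 15)) >= -1e-12))
  expect_true(all(diff(drought_factor(100, 0:60, 15)) >= -1e-12))
  expect_true(all(drought_factor(runif(200, 0, 203), sample(0:90, 200, TRUE),
                                 runif(200, 0, 60)) <= 10))
})

test_that("FFDI follows the Mark 5 closed form with the DF = 0 convention", {
  expect_equal(ffdi(30, 20, 25, 0), 0)
  # +29.6 km/h of wind multiplies FFDI by exp(0.0234 * 29.6) ~ 2
  base <- ffdi(30, 20, 10, 8)
  expect_equal(ffdi(30, 20, 10 + 29.6, 8) / base, exp(0.0234 * 29.6),
               tolerance = 1e-12)
  expect_equal(ffdi(30, 20, 10 + 29.6, 8) / base, 2, tolerance = 1e-3)
  # more humid is safer
  expect_lt(ffdi(30, 60, 25, 8), ffdi(30, 30, 25, 8))
  expect_error(ffdi(30, 120, 10, 8), "\\[0, 100\\]")
  expect_error(ffdi(30, 50, -1, 8), "non-negative")
})

test_that("FFDI monotonicity holds at 1000 random weather states", {
  set.seed(101)
  n <- 1000
  t <- runif(n, 0, 48); rh <- runif(n, 1, 99)
  v <- runif(n, 0, 90); df <- runif(n, 0.5, 9.5)
  f0 <- ffdi(t, rh, v, df)
  expect_true(all(ffdi(t + 1, rh, v, df) > f0))
  expect_true(all(ffdi(t, rh, v + 1, df) > f0))
  expect_true(all(ffdi(t, rh - 1, v, df) > f0))
  expect_true(all(ffdi(t, rh, v, pmin(df + 0.5, 10)) > f0))
  expect_true(all(f0 >= 0))
})

test_that("C-Haines components follow the two-part formula with caps", {
  # zero lapse, saturated at 850 hPa
  z <- chaines(10, 10, 10)
  expect_equal(z$ca, -2); expect_equal(z$cb, -1); expect_equal(z$ch, -3)
  # mid-range hand evaluation: CA = 0.5*10 - 2 = 3, DD = 15 -> CB = 4
  m <- chaines(20, 10, 5)
  expect_equal(m$ca, 3); expect_equal(m$cb, 4); expect_equal(m$ch, 7)
  # the humidity excess above 5 is halved: DD = 21 -> CB = 6 -> 5.5
  expect_equal(chaines(21, 10, 0)$cb, 5.5)
  # dewpoint-depression cap at 30: further drying changes nothing
  expect_equal(chaines(40, 20, 10)$cb, chaines(40, 20, -20)$cb)
  expect_error(chaines(10, 5, 12), "dewpoint")
})

test_that("CA depends only on the lapse, CB only on the dewpoint depression", {
  set.seed(5)
  t850 <- runif(50, 0, 25); t700 <- t850 - runif(50, 0, 15)
  dd <- runif(50, 0, 25)
  a <- chaines(t850, t700, t850 - dd)
  b <- chaines(t850 + 3, t700 + 3, t850 + 3 - dd)  # shift both temps
  expect_equal(a$ca, b$ca, tolerance = 1e-12)
  expect_equal(a$cb, b$cb, tolerance = 1e-12)
})

test_that("dry lightning needs lightning and rain under the threshold", {
  expect_true(dry_lightning(TRUE, 1.0))
  expect_false(dry_lightning(TRUE, 3.0))
  expect_false(dry_lightning(FALSE, 0))
  expect_true(dry_lightning(TRUE, 2.49))
  expect_false(dry_lightning(TRUE, 2.5))   # threshold is exclusive above
  # subset property on random fields
  set.seed(3)
  l <- runif(500) < 0.3; r <- rexp(500, 1 / 2)
  expect_true(all(which(dry_lightning(l, r)) %in% which(l)))
})

test_that("threshold day counts use inclusive comparison and nest", {
  dates <- seq(as.Date("2000-07-01"), as.Date("2001-06-30"), by = "day")
  vals <- rep(0, length(dates))
  vals[10:13] <- c(10, 26, 50, 70)
  cube <- array(vals, c(length(dates), 1, 1))
  d25 <- days_over_threshold(cube, dates, threshold = 25)
  d50 <- days_over_threshold(cube, dates, threshold = 50)
  expect_equal(d25$days, 3)
  expect_equal(d50$days, 2)

  # all-zero cube
  expect_equal(days_over_threshold(array(0, c(length(dates), 1, 1)),
                                   dates, threshold = 25)$days, 0)

  # nesting on a random multi-year cube, both modes
  set.seed(9)
  dates2 <- seq(as.Date("1999-07-01"), as.Date("2002-06-30"), by = "day")
  cube2 <- array(rexp(length(dates2) * 4, 1 / 20), c(length(dates2), 2, 2))
  for (mode in c("forest_mean", "per_pixel")) {
    a <- days_over_threshold(cube2, dates2, threshold = 25, mode = mode)
    b <- days_over_threshold(cube2, dates2, threshold = 50, mode = mode)
    expect_true(all(b$days <= a$days))
  }

  # incomplete fire years are dropped by default
  part <- seq(as.Date("2000-07-01"), as.Date("2001-09-30"), by = "day")
  got <- days_over_threshold(array(0, c(length(part), 1, 1)), part,
                             threshold = 25)
  expect_identical(got$fire_year, 2000L)
})

test_that("epoch change recovers an injected step exactly and is null on stationary climate", {
  g <- grid_spec(3, 3)
  dates <- seq(as.Date("1980-01-01"), as.Date("2019-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  base <- array(15, c(length(dates), 3, 3))
  stepped <- base
  stepped[yr >= 2000, , ] <- 16
  ec <- epoch_change(stepped, dates)
  expect_equal(max(abs(ec$change - 1)), 0, tolerance = 1e-12)

  # stationary noise: change within a 4-sigma sampling envelope
  set.seed(12)
  sd_day <- 3
  noisy <- base + array(rnorm(length(base), 0, sd_day), dim(base))
  ecn <- epoch_change(noisy, dates)
  n_per_epoch <- sum(yr <= 1999)
  env <- 4 * sd_day * sqrt(2 / n_per_epoch)
  expect_true(all(abs(ecn$change) < env))

  # dry-lightning frequency doubling: +100%
  occ <- array(FALSE, c(length(dates), 1, 1))
  occ[yr <= 1999, 1, 1] <- rep(c(TRUE, rep(FALSE, 9)), length.out = sum(yr <= 1999))
  occ[yr >= 2000, 1, 1] <- rep(c(TRUE, TRUE, rep(FALSE, 8)),
                               length.out = sum(yr >= 2000))
  ecd <- epoch_change(occ, dates)
  expect_equal(ecd$percent_change[1, 1], 100, tolerance = 1)

  expect_error(epoch_change(base[yr <= 2005, , , drop = FALSE],
                            dates[yr <= 2005]), "missing years")
})

test_that("the index cube pipeline produces coherent fields", {
  g <- grid_spec(2, 2)
  wp <- weather_gen_params(noise_sd = c(tmax = 2, rain = 4, rh = 8,
                                        wind = 4),
                           lightning_rate = 0.05, seed = 17)
  wx <- simulate_weather(wp, g, 2000:2001)
  idx <- fire_weather_indices(wx)
  expect_true(all(idx$kbdi >= 0 & idx$kbdi <= 203.2 + 1e-9))
  expect_true(all(idx$df >= 0 & idx$df <= 10))
  expect_true(all(idx$ffdi >= 0))
  expect_true(all(idx$dry_lightning <= wx$lightning))  # subset
  expect_identical(dim(idx$ffdi), dim(wx$tmax))
})
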