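test_that("per-pixel wildfire frequency is fires over record years, wildfires only", {
  h <- make_history(years = 1930:2019,
                    wildfire_events = c(lapply(1930 + 10 * (0:8), function(y)
                      c(1, 1, y)), list(c(2, 1, 1950))),
                    prescribed_events = list(c(2, 1, 1960), c(3, 3, 1940)))
  p <- estimate_p(h)
  expect_equal(p[1, 1], 9 / 90)
  expect_equal(p[2, 1], 1 / 90)   # prescribed burn not counted
  expect_true(is.na(p[3, 3]))     # prescribed-only pixel is ineligible
  expect_true(is.na(p[2, 2]))     # never burned
})

test_that("geometric initializer is the exact geometric quantile with a floor of 1", {
  expect_identical(geometric_init(0.75, 0.5), 2L)  # ln(.25)/ln(.5) = 2
  expect_identical(geometric_init(1e-12, 0.3), 1L) # u -> 0+ gives 1
  expect_identical(geometric_init(0.5, 0.2),
                   as.integer(ceiling(log(0.5) / log(0.8))))
  expect_error(geometric_init(0, 0.5), "inside")
  expect_error(geometric_init(1, 0.5), "inside")
  expect_error(geometric_init(0.5, 0), "inside")
  expect_error(geometric_init(0.5, 1), "inside")
  # floor convention floors at 1 instead of colliding with the 0 code
  expect_identical(geometric_init(1e-12, 0.3, rounding = "floor"), 1L)
})

test_that("initializer draws match the geometric pmf and mean", {
  set.seed(31)
  p <- 0.1
  n <- 2e5
  draws <- geometric_init(runif(n), p)
  se <- sqrt((1 - p) / p^2 / n)
  expect_lt(abs(mean(draws) - 1 / p), 3 * se)
  # chi-square against the closed-form pmf P(k) = p (1-p)^(k-1)
  kmax <- 60
  obs <- tabulate(pmin(draws, kmax + 1), nbins = kmax + 1)
  probs <- p * (1 - p)^(0:(kmax - 1))
  probs <- c(probs, 1 - sum(probs))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
  # and against an independent rgeom-based sample
  set.seed(32)
  ref <- rgeom(n, p) + 1L
  expect_lt(abs(mean(draws) - mean(ref)), 4 * se)
})

test_that("reconstruction resets on fires, increments between, and masks never-burned pixels", {
  h <- make_history(years = 1930:1949,
                    wildfire_events = list(c(1, 1, 1930), c(1, 1, 1940),
                                           c(2, 2, 1945)))
  yg <- yslf_reconstruct(h, seed = 1)
  expect_identical(as.integer(yg$yslf[1, 1, ]),
                   c(0:9, 0:9))
  expect_true(all(is.na(yg$yslf[3, 3, ])))        # never burned: masked
  expect_true(yg$eligible[2, 2] && !yg$eligible[3, 3])
  # pixel (2,2): initializer value incremented until the 1945 reset
  pre <- yg$yslf[2, 2, 1:15]
  expect_true(all(diff(pre) == 1L))
  expect_identical(yg$yslf[2, 2, 16], 0L)
  # provenance flips to observed at the first in-record fire
  expect_true(all(yg$estimated[2, 2, 1:15]))
  expect_false(any(yg$estimated[2, 2, 16:20]))
  expect_false(any(yg$estimated[1, 1, ]))         # burned in the origin year
})

test_that("zeros coincide exactly with recorded wildfires on eligible pixels", {
  g <- grid_spec(12, 12)
  h <- simulate_fire_history(fire_process_params(g, 1960, 1999, p = 0.08,
                                                 seed = 3))
  yg <- yslf_reconstruct(h, seed = 4)
  for (t in seq_along(yg$years)) {
    z <- yg$yslf[, , t] == 0L
    z[is.na(z)] <- FALSE
    expect_identical(z, h$wildfire[, , t] & yg$eligible)
  }
  # non-negative integers throughout the eligible set
  expect_true(all(yg$yslf[!is.na(yg$yslf)] >= 0L))
})

test_that("observed pixel-years are seed-independent; the whole grid is seed-reproducible", {
  g <- grid_spec(10, 10)
  h <- simulate_fire_history(fire_process_params(g, 1950, 1999, p = 0.1,
                                                 seed = 5))
  a <- yslf_reconstruct(h, seed = 1)
  b <- yslf_reconstruct(h, seed = 2)
  obs <- !a$estimated & !is.na(a$yslf)
  expect_identical(a$yslf[obs], b$yslf[obs])
  expect_false(identical(a$yslf, b$yslf))  # initializer tails differ
  expect_identical(yslf_reconstruct(h, seed = 1), a)
})

test_that("gap years in the stack are rejected", {
  h <- make_history(years = 1930:1939,
                    wildfire_events = list(c(1, 1, 1930)))
  h$years <- c(1930:1935, 1937:1940)
  expect_error(yslf_reconstruct(h), "gap")
})

test_that("decadal summary takes mean and SD across the decade's annual spatial means", {
  # constant surface k all decade: k with zero SD
  k <- 7L
  yg <- structure(list(
    yslf = array(k, c(2, 2, 10)),
    estimated = array(FALSE, c(2, 2, 10)),
    eligible = matrix(TRUE, 2, 2),
    years = 2000:2009, grid = grid_spec(2, 2),
    p = matrix(0.1, 2, 2)), class = "yslf_grid")
  s <- decadal_summary(yg, 2000)
  expect_equal(s$mean, 7)
  expect_equal(s$sd, 0)

  # one fire everywhere mid-decade: that year's spatial mean is 0, SD > 0
  h <- make_history(rows = 2, cols = 2, years = 2000:2009,
                    wildfire_events = list(c(1, 1, 2005), c(1, 2, 2005),
                                           c(2, 1, 2005), c(2, 2, 2005)))
  yr <- yslf_reconstruct(h, seed = 9)
  am <- yslf_annual_means(yr)
  expect_equal(am$mean_yslf[am$year == 2005], 0)
  s2 <- decadal_summary(yr, 2000)
  expect_gt(s2$sd, 0)
  expect_error(decadal_summary(yr, 2050), "outside")
})

test_that("final-decade mean tracks the stationary mean on a synthetic history", {
  g <- grid_spec(60, 60)
  p <- 0.05
  h <- simulate_fire_history(fire_process_params(g, 1930, 2019, p = p,
                                                 seed = 21))
  yg <- yslf_reconstruct(h, seed = 22)
  s <- decadal_summary(yg, 2010)
  # independent oracle at the same size and conditions
  or <- yslf_oracle_decade_mean(p, 3600, 90, 81:90, seed = 55)
  expect_equal(s$mean, mean(or$means), tolerance = 0.08)
})

test_that("burned-at-least-once fractions match the closed-form complement", {
  # class entirely burned once
  h <- make_history(rows = 2, cols = 2, years = 2000:2004,
                    wildfire_events = list(c(1, 1, 2001), c(1, 2, 2002),
                                           c(2, 1, 2003), c(2, 2, 2004)))
  cls <- matrix("all", 2, 2)
  expect_equal(burned_fraction_by_class(h, cls)$burned_fraction, 1)

  # no fires at all
  h0 <- make_history(rows = 2, cols = 2, years = 2000:2004)
  expect_equal(burned_fraction_by_class(h0, cls)$burned_fraction, 0)

  # stationary p = 0.01 over 90 years: 1 - 0.99^90 within 3 SE
  g <- grid_spec(100, 100)
  hs <- simulate_fire_history(fire_process_params(g, 1930, 2019, p = 0.01,
                                                  seed = 13))
  f <- burned_fraction_by_class(hs, matrix("forest", 100, 100))
  expected <- 1 - 0.99^90
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_lt(abs(f$burned_fraction - expected), 3 * se)

  expect_error(burned_fraction_by_class(h, matrix("x", 3, 3)), "aligned")
})
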