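# Shared fixtures and independent oracles for the test suite.

# A tiny fire_history built by hand (not through the simulator), with
# full control over which pixel burns when.
make_history <- function(rows = 3, cols = 3, years = 1930:1939,
                         wildfire_events = list(),
                         prescribed_events = list(),
                         cellsize = 0.01, origin_lat = 0) {
  g <- grid_spec(rows, cols, origin_lat = origin_lat, origin_lon = 0,
                 cellsize = cellsize)
  ny <- length(years)
  wf <- array(FALSE, c(rows, cols, ny))
  pb <- array(FALSE, c(rows, cols, ny))
  for (ev in wildfire_events)         # ev = c(row, col, year)
    wf[ev[1], ev[2], match(ev[3], years)] <- TRUE
  for (ev in prescribed_events)
    pb[ev[1], ev[2], match(ev[3], years)] <- TRUE
  structure(list(wildfire = wf, prescribed = pb, years = years, grid = g,
                 p_true = matrix(NA_real_, rows, cols)),
            class = "fire_history")
}

# Hand-built monthly burned product: events = list(c(row, col, year, month))
make_monthly <- function(rows = 2, cols = 2, fire_year = 2000,
                         events = list(), cellsize = 0.01,
                         origin_lat = 0) {
  g <- grid_spec(rows, cols, origin_lat = origin_lat, origin_lon = 0,
                 cellsize = cellsize)
  cal <- data.frame(year = c(rep(fire_year, 6), rep(fire_year + 1, 6)),
                    month = c(7:12, 1:6))
  b <- array(FALSE, c(rows, cols, 12))
  for (ev in events) {
    k <- which(cal$year == ev[3] & cal$month == ev[4])
    b[ev[1], ev[2], k] <- TRUE
  }
  structure(list(burned = b, months = cal, grid = g, source = "fixture"),
            class = "monthly_burned")
}

# Independent YSLF oracle: last-burn-index bookkeeping over a Bernoulli
# burn matrix with an rgeom-based initializer drawn, as the method
# defines, from each pixel's own estimated fire frequency (k fires / n
# years). Returns the mean YSLF over eligible pixels for each requested
# year index, plus the eligible fraction. Deliberately avoids the
# package's increment/reset recursion and its inverse-CDF initializer.
yslf_oracle_decade_mean <- function(p, n_pixels, n_years, year_idx, seed) {
  set.seed(seed)
  burns <- matrix(stats::runif(n_pixels * n_years) < p, n_pixels, n_years)
  eligible <- rowSums(burns) > 0
  p_hat <- pmax(rowSums(burns), 1L) / n_years
  init <- stats::rgeom(n_pixels, p_hat) + 1L # P(k) = p (1-p)^(k-1), k >= 1
  lastburn <- rep(0L, n_pixels)
  means <- numeric(length(year_idx))
  names(means) <- year_idx
  for (t in seq_len(n_years)) {
    lastburn[burns[, t]] <- t
    if (t %in% year_idx) {
      yslf <- ifelse(lastburn > 0L, t - lastburn, init + (t - 1L))
      means[as.character(t)] <- mean(yslf[eligible])
    }
  }
  list(means = means, eligible_fraction = mean(eligible))
}

# Daily weather climatology replicated by hand (same functional form the
# generator documents; used for the exact zero-noise checks).
expected_climatology <- function(doy, mean, amplitude, peak_doy) {
  mean + amplitude * cos(2 * pi * (doy - peak_doy) / 365)
}
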