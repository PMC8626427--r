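#' One daily step of the Keetch-Byram drought index
#'
#' The KBDI tracks cumulative soil moisture deficit in mm equivalent on
#' [0, 203.2]. Rainfall first refills a 5.08 mm interception allowance
#' per rain event (consecutive wet days share one allowance); the excess
#' ("effective rainfall") reduces the index. The daily
#' evapotranspiration increment depends on the running index, the day's
#' maximum temperature and the site's mean annual rainfall.
#'
#' @param kbdi_prev previous day's index, in [0, 203.2]; vectors and
#'   matrices are supported elementwise.
#' @param rain_mm daily rainfall (>= 0).
#' @param tmax_c daily maximum temperature (deg C).
#' @param annual_rain_mm mean annual rainfall (mm).
#' @param carry_prev rainfall already intercepted within the current rain
#'   event (mm, from the previous day's return).
#' @return List: `kbdi` (updated index) and `carry` (interception state
#'   to pass into the next day).
#' @export
kbdi_update <- function(kbdi_prev, rain_mm, tmax_c, annual_rain_mm,
                        carry_prev = 0) {
  k <- ft_const$kbdi
  if (any(!is.finite(rain_mm)) || any(rain_mm < 0))
    stop("rainfall must be finite and non-negative")
  if (any(kbdi_prev < -1e-9) || any(kbdi_prev > k$max_mm + 1e-9))
    stop("kbdi_prev outside [0, 203.2]")
  # interception allowance resets on a dry day
  carry <- ifelse(rain_mm > 0, carry_prev, 0)
  eff <- pmax(0, rain_mm - pmax(0, k$interception - carry))
  carry_out <- ifelse(rain_mm > 0, pmin(k$interception, carry + rain_mm), 0)
  q <- pmax(0, kbdi_prev - eff)
  et <- 1e-3 * (k$max_mm - q) *
    (k$et_c1 * exp(k$et_c2 * tmax_c + k$et_c3) - k$et_c4) /
    (1 + k$et_d1 * exp(-k$et_d2 * annual_rain_mm))
  et <- pmax(et, 0)
  list(kbdi = pmin(pmax(q + et, 0), k$max_mm), carry = carry_out)
}

#' Run the KBDI recursion over a daily series
#'
#' @param rain_mm,tmax_c daily vectors (or `(n_days, rows, cols)` arrays).
#' @param annual_rain_mm mean annual rainfall (scalar or matrix).
#' @param kbdi0 initial index value (default half capacity).
#' @return Numeric object matching the input shape with the daily KBDI.
#' @export
kbdi_series <- function(rain_mm, tmax_c, annual_rain_mm,
                        kbdi0 = ft_const$kbdi$max_mm / 2) {
  is_cube <- length(dim(rain_mm)) == 3L
  nd <- if (is_cube) dim(rain_mm)[1] else length(rain_mm)
  out <- if (is_cube) array(NA_real_, dim(rain_mm)) else numeric(nd)
  state <- kbdi0
  carry <- 0
  for (d in seq_len(nd)) {
    r <- if (is_cube) rain_mm[d, , ] else rain_mm[d]
    tm <- if (is_cube) tmax_c[d, , ] else tmax_c[d]
    step <- kbdi_update(state, r, tm, annual_rain_mm, carry)
    state <- step$kbdi
    carry <- step$carry
    if (is_cube) out[d, , ] <- state else out[d] <- state
  }
  out
}

#' Griffiths drought factor
#'
#' Fuel-availability multiplier on [0, 10] combining the standing soil
#' moisture deficit (KBDI) with the recency and size of the last
#' significant rain event (>= 2 mm): long dry spells at high KBDI push
#' the factor to 10; a large recent rain event pulls it towards 0.
#'
#' @param kbdi current KBDI (mm equivalent).
#' @param days_since_rain days since the last significant rain event.
#' @param last_event_rain_mm rainfall total of that event (mm).
#' @return Drought factor in [0, 10]; elementwise over inputs.
#' @export
drought_factor <- function(kbdi, days_since_rain, last_event_rain_mm) {
  k <- ft_const$df
  if (any(kbdi < -1e-9) || any(kbdi > ft_const$kbdi$max_mm + 1e-9))
    stop("kbdi outside [0, 203.2]")
  N <- pmax(days_since_rain, 0)
  P <- pmax(last_event_rain_mm, 0)
  xraw <- ifelse(P < k$event_mm, 1,
                 N^k$x_n_exp / (N^k$x_n_exp + P - k$event_mm))
  x <- pmin(pmax(xraw, 0), 1)
  df <- k$k1 * (1 - exp(-(kbdi + k$k2) / k$k3)) *
    (k$r1 * x^2 + x) / (k$r2 * x^2 + x + 1)
  pmin(pmax(df, 0), k$cap)
}

#' McArthur Forest Fire Danger Index (Mark 5 meter)
#'
#' `FFDI = 2 * exp(-0.450 + 0.987 ln(DF) - 0.0345 RH + 0.0338 T
#' + 0.0234 V)` with drought factor DF, relative humidity RH (%), daily
#' maximum temperature T (deg C) and 10 m wind speed V (km/h). FFDI >= 25
#' is the Very High danger class, >= 50 Severe. At DF = 0 the index is
#' defined as 0 (no available fuel).
#'
#' @param tmax_c,rh_pct,wind_kmh,df elementwise inputs; RH in [0, 100],
#'   wind >= 0, DF in [0, 10].
#' @return FFDI values (>= 0).
#' @export
ffdi <- function(tmax_c, rh_pct, wind_kmh, df) {
  if (any(rh_pct < 0) || any(rh_pct > 100)) stop("RH must be in [0, 100]")
  if (any(wind_kmh < 0)) stop("wind speed must be non-negative")
  if (any(df < 0) || any(df > ft_const$df$cap + 1e-9))
    stop("drought factor must be in [0, 10]")
  f <- ft_const$ffdi
  out <- f$scale * exp(f$a0 + f$a_lndf * log(pmax(df, 1e-300)) +
                         f$a_rh * rh_pct + f$a_t * tmax_c +
                         f$a_v * wind_kmh)
  out[df == 0] <- 0
  out
}

#' Continuous Haines index
#'
#' Pyroconvection risk index summing a lower-tropospheric stability
#' component `CA = 0.5 (T850 - T700) - 2` and a humidity component built
#' from the 850 hPa dewpoint depression `DD = T850 - Td850`:
#' `CB = DD/3 - 1` with DD capped at 30 deg C and CB excess above 5
#' halved. Higher values indicate greater risk of fire-generated
#' thunderstorms (pyroCb).
#'
#' @param t850,t700 temperatures at 850 and 700 hPa (deg C).
#' @param td850 dewpoint temperature at 850 hPa (deg C); must not exceed
#'   `t850`.
#' @return List with components `ca`, `cb` and `ch = ca + cb`.
#' @export
chaines <- function(t850, t700, td850) {
  if (any(td850 > t850 + 1e-9))
    stop("850 hPa dewpoint above the 850 hPa temperature")
  k <- ft_const$chaines
  ca <- k$ca_scale * (t850 - t700) - k$ca_offset
  dd <- pmin(t850 - td850, k$dd_cap)
  cb <- dd * k$cb_scale - k$cb_offset
  cb <- ifelse(cb > k$cb_knee, k$cb_knee + (cb - k$cb_knee) / 2, cb)
  list(ca = ca, cb = cb, ch = ca + cb)
}

#' Dry-lightning flag
#'
#' A dry-lightning day is a lightning day with rainfall below the
#' threshold (about 2.5 mm): such days carry a higher-than-average chance
#' that the lightning ignites a wildfire.
#'
#' @param lightning_flag logical, lightning occurred.
#' @param rain_mm daily rainfall (>= 0).
#' @param threshold_mm rainfall threshold (default 2.5 mm).
#' @return Logical flag, elementwise.
#' @export
dry_lightning <- function(lightning_flag, rain_mm,
                          threshold_mm = ft_const$dry_lightning_rain_mm) {
  if (any(rain_mm < 0)) stop("rainfall must be non-negative")
  lightning_flag & (rain_mm < threshold_mm)
}

#' Compute daily FFDI and C-Haines cubes from a weather cube
#'
#' Runs the KBDI recursion, Griffiths drought factor, FFDI, C-Haines and
#' dry-lightning flag over a [simulate_weather()] cube (or any list with
#' the same fields).
#'
#' @param wx a `weather_cube`.
#' @param kbdi0 initial KBDI.
#' @return List of arrays `(n_days, rows, cols)`: `kbdi`, `df`, `ffdi`,
#'   `chaines`, logical `dry_lightning`, plus `dates` and `grid`.
#' @export
fire_weather_indices <- function(wx, kbdi0 = ft_const$kbdi$max_mm / 2) {
  stopifnot(inherits(wx, "weather_cube") || is.list(wx))
  nd <- length(wx$dates)
  annual_rain <- apply(wx$rain, c(2, 3), mean) * 365.25
  kb <- kbdi_series(wx$rain, wx$tmax, annual_rain, kbdi0 = kbdi0)
  dims <- dim(wx$rain)
  dfc <- array(NA_real_, dims)
  ffc <- array(NA_real_, dims)
  ev <- ft_const$df$event_mm
  days_since <- matrix(0, dims[2], dims[3])
  last_event <- matrix(0, dims[2], dims[3])   # running event accumulation
  event_total <- matrix(0, dims[2], dims[3])  # size of last completed event
  for (d in seq_len(nd)) {
    r <- wx$rain[d, , ]
    wet <- r >= ev
    last_event <- ifelse(wet, last_event + r, 0)
    event_total <- ifelse(wet, last_event, event_total)
    days_since <- ifelse(wet, 0, days_since + 1)
    dfd <- drought_factor(kb[d, , ], days_since, event_total)
    dfc[d, , ] <- dfd
    ffc[d, , ] <- ffdi(wx$tmax[d, , ], wx$rh[d, , ], wx$wind[d, , ], dfd)
  }
  ch <- chaines(wx$t850, wx$t700, wx$td850)$ch
  dl <- dry_lightning(wx$lightning, wx$rain)
  list(kbdi = kb, df = dfc, ffdi = ffc, chaines = ch, dry_lightning = dl,
       dates = wx$dates, grid = wx$grid)
}

#' Days per fire year with FFDI at or above a threshold
#'
#' Counts, for each complete July-June fire year, the days whose index
#' equals or exceeds the threshold (inclusive). The default mode reduces
#' the daily field to its spatial mean over the forest mask and counts
#' threshold days of that single national/regional series; the
#' `"per_pixel"` mode counts exceedance days per pixel and then averages
#' the counts spatially.
#'
#' @param cube daily index array `(n_days, rows, cols)`.
#' @param dates Date vector of length `n_days`.
#' @param mask logical forest mask (default all cells).
#' @param threshold inclusive threshold (e.g. 25 or 50 for FFDI).
#' @param mode `"forest_mean"` (default) or `"per_pixel"`.
#' @param keep_partial keep incomplete fire years (default FALSE: they
#'   are dropped).
#' @return Data frame `fire_year`, `days`, with attribute `mode`.
#' @export
days_over_threshold <- function(cube, dates, mask = NULL, threshold = 25,
                                mode = c("forest_mean", "per_pixel"),
                                keep_partial = FALSE) {
  mode <- match.arg(mode)
  nd <- dim(cube)[1]
  stopifnot(length(dates) == nd)
  if (is.null(mask)) mask <- matrix(TRUE, dim(cube)[2], dim(cube)[3])
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  fy <- assign_fire_year(yr, mo)
  fy_months <- tapply(mo, fy, function(m) length(unique(m)))
  ok_years <- as.integer(names(fy_months))[fy_months == 12L]
  sel_pix <- which(mask)
  flat <- matrix(cube, nrow = nd)[, sel_pix, drop = FALSE]
  out <- lapply(sort(unique(fy)), function(y) {
    if (!(y %in% ok_years) && !keep_partial) return(NULL)
    rows <- fy == y
    if (mode == "forest_mean") {
      daily <- rowMeans(flat[rows, , drop = FALSE])
      days <- sum(daily >= threshold)
    } else {
      days <- mean(colSums(flat[rows, , drop = FALSE] >= threshold))
    }
    data.frame(fire_year = y, days = days)
  })
  res <- do.call(rbind, out)
  attr(res, "mode") <- mode
  res
}

#' Epoch-change map of a daily field
#'
#' Per-pixel difference of means between two calendar-year epochs
#' (defaults: 1980-1999 vs 2000-2019; pass `epoch2 = c(2000, 2016)` for
#' fields only available to 2016, as with dry lightning). For logical
#' (occurrence) fields the relative frequency change in percent is also
#' returned.
#'
#' @param cube daily array `(n_days, rows, cols)`; may be logical.
#' @param dates Date vector.
#' @param epoch1,epoch2 inclusive calendar-year ranges `c(first, last)`.
#' @return List: `change` matrix (mean epoch2 - mean epoch1),
#'   `mean1`, `mean2`, and for logical cubes `percent_change`
#'   (100 * (mean2/mean1 - 1), NA where epoch1 frequency is 0).
#' @export
epoch_change <- function(cube, dates, epoch1 = c(1980, 1999),
                         epoch2 = c(2000, 2019)) {
  yr <- as.integer(format(dates, "%Y"))
  in1 <- yr >= epoch1[1] & yr <= epoch1[2]
  in2 <- yr >= epoch2[1] & yr <= epoch2[2]
  if (!any(in1) || !any(in2)) stop("an epoch has no days in the record")
  miss1 <- setdiff(epoch1[1]:epoch1[2], yr)
  miss2 <- setdiff(epoch2[1]:epoch2[2], yr)
  if (length(miss1) || length(miss2))
    stop(sprintf("missing years in the record: %s",
                 paste(c(miss1, miss2), collapse = ", ")))
  m1 <- apply(cube[in1, , , drop = FALSE], c(2, 3), mean)
  m2 <- apply(cube[in2, , , drop = FALSE], c(2, 3), mean)
  out <- list(change = m2 - m1, mean1 = m1, mean2 = m2)
  if (is.logical(cube)) {
    pc <- 100 * (m2 / m1 - 1)
    pc[m1 == 0] <- NA_real_
    out$percent_change <- pc
  }
  out
}
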