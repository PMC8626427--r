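#' Parameters for the synthetic fire-occurrence process
#'
#' The truth process behind every downstream test: each pixel burns
#' independently each year as a Bernoulli trial with annual wildfire
#' probability `p` (scalar or per-pixel map), at most one wildfire per
#' pixel per year. Prescribed burns are generated as a separate cause
#' layer with a target annual area. An optional logistic weather coupling
#' modulates `p` by a standardized annual fire-weather summary.
#'
#' @param grid a [grid_spec()].
#' @param start_year,end_year record span (calendar years, inclusive).
#' @param p annual wildfire probability: scalar in (0,1) or `rows x cols`
#'   matrix with all entries in (0,1).
#' @param prescribed_mean_km2 target mean annual prescribed-burn area
#'   (km^2); 0 disables the prescribed layer.
#' @param prescribed_sd_km2 year-to-year SD of the prescribed-burn area.
#' @param coupling_beta logistic coupling coefficient; 0 (default) keeps
#'   the process stationary Bernoulli so closed-form expectations hold.
#' @param seed integer seed; fixes every draw (bit-reproducible reruns).
#' @return An object of class `fire_process_params`.
#' @export
fire_process_params <- function(grid, start_year = 1930, end_year = 2019,
                                p = 0.02, prescribed_mean_km2 = 0,
                                prescribed_sd_km2 = 0, coupling_beta = 0,
                                seed = 1L) {
  stopifnot(is_grid_spec(grid))
  if (start_year > end_year) stop("start_year must be <= end_year")
  pm <- if (is.matrix(p)) p else matrix(p, grid$rows, grid$cols)
  if (!all(dim(pm) == c(grid$rows, grid$cols)))
    stop("p map dimensions must match the grid")
  if (anyNA(pm) || any(!is.finite(pm)) || any(pm <= 0) || any(pm >= 1))
    stop("fire probability p must be finite and inside (0, 1) everywhere")
  if (prescribed_mean_km2 < 0 || prescribed_sd_km2 < 0)
    stop("prescribed-burn area parameters must be non-negative")
  structure(list(grid = grid, start_year = as.integer(start_year),
                 end_year = as.integer(end_year), p = pm,
                 prescribed_mean_km2 = prescribed_mean_km2,
                 prescribed_sd_km2 = prescribed_sd_km2,
                 coupling_beta = coupling_beta, seed = as.integer(seed)),
            class = "fire_process_params")
}

# Deterministic substream seed from a top-level seed and a stream name.
# Keeps every generator independent while one seed drives the whole run.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate an annual fire-history stack
#'
#' Draws the wildfire occurrence stack (one logical matrix per year) from
#' independent Bernoulli(p) trials per pixel-year, plus an optional
#' prescribed-burn layer hitting a target annual area, and returns the
#' true `p` map alongside for parameter-recovery tests.
#'
#' When `weather_summary` is supplied (a numeric vector, one standardized
#' value per year) and `coupling_beta != 0`, year `t` uses
#' `plogis(qlogis(p) + beta * z_t)` instead of `p`.
#'
#' @param params a [fire_process_params()].
#' @param weather_summary optional standardized annual fire-weather
#'   summary used by the logistic coupling.
#' @return An object of class `fire_history`: list with `wildfire` and
#'   `prescribed` logical arrays `(rows, cols, n_years)`, `years`, `grid`,
#'   and the true probability map `p_true`.
#' @export
simulate_fire_history <- function(params, weather_summary = NULL) {
  stopifnot(inherits(params, "fire_process_params"))
  years <- params$start_year:params$end_year
  ny <- length(years)
  g <- params$grid
  if (!is.null(weather_summary) && length(weather_summary) != ny)
    stop("weather_summary must have one value per record year")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(params$seed, "wildfire"))
  wf <- array(FALSE, c(g$rows, g$cols, ny))
  for (t in seq_len(ny)) {
    pt <- params$p
    if (!is.null(weather_summary) && params$coupling_beta != 0) {
      pt <- stats::plogis(stats::qlogis(params$p) +
                            params$coupling_beta * weather_summary[t])
    }
    wf[, , t] <- matrix(stats::runif(g$rows * g$cols) < pt, g$rows, g$cols)
  }
  pb <- array(FALSE, c(g$rows, g$cols, ny))
  if (params$prescribed_mean_km2 > 0) {
    set.seed(substream_seed(params$seed, "prescribed"))
    areas <- cell_area_km2(g)
    mean_cell <- mean(areas)
    for (t in seq_len(ny)) {
      target <- max(0, stats::rnorm(1, params$prescribed_mean_km2,
                                    params$prescribed_sd_km2))
      ncell <- min(g$rows * g$cols, round(target / mean_cell))
      if (ncell > 0) {
        idx <- sample.int(g$rows * g$cols, ncell)
        sl <- pb[, , t]
        sl[idx] <- TRUE
        pb[, , t] <- sl
      }
    }
  }
  structure(list(wildfire = wf, prescribed = pb, years = years, grid = g,
                 p_true = params$p),
            class = "fire_history")
}

#' @export
print.fire_history <- function(x, ...) {
  cat(sprintf("fire_history: %d x %d grid, years %d-%d (%d), %d wildfire and %d prescribed pixel-events\n",
              x$grid$rows, x$grid$cols, x$years[1], x$years[length(x$years)],
              length(x$years), sum(x$wildfire), sum(x$prescribed)))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Parameters for the synthetic daily weather generator
#'
#' Each variable follows `mean + amplitude * cos(2*pi*(doy - peak_doy)/365)
#' + trend + noise`, with Austral seasonality (temperature peaks in
#' mid-January, DJF). Trends are linear in time, expressed per decade.
#' Relative humidity is clamped to [0, 100], rainfall to >= 0, and the
#' 850 hPa dewpoint never exceeds the 850 hPa temperature (the dewpoint
#' depression is generated as a non-negative quantity).
#'
#' @param means,amplitudes named numeric vectors for variables
#'   `tmax` (deg C), `rh` (%), `wind` (km/h), `rain` (mm/day),
#'   `t850`, `t700` (deg C) and `dewpoint_depression_850` (deg C, >= 0).
#'   Amplitudes are the seasonal half-ranges; humidity and rainfall peak in
#'   July (austral winter), the rest in January.
#' @param trends_per_decade named numeric vector of linear trends (units
#'   per decade), default all zero.
#' @param noise_sd named numeric vector of daily Gaussian noise SDs,
#'   default all zero.
#' @param synoptic_share fraction of the noise variance that is shared
#'   across the whole grid on a given day (weather systems are larger
#'   than the domain, so hot/dry extremes are spatially coherent);
#'   the remainder is independent pixel noise. In [0, 1], default 0.8.
#' @param lightning_rate daily lightning-day probability per pixel.
#' @param seed integer seed.
#' @return An object of class `weather_gen_params`.
#' @export
weather_gen_params <- function(means = c(tmax = 20, rh = 60, wind = 15,
                                         rain = 2.2, t850 = 12, t700 = 2,
                                         dewpoint_depression_850 = 8),
                               amplitudes = c(tmax = 8, rh = -12, wind = 3,
                                              rain = -1.2, t850 = 6,
                                              t700 = 5,
                                              dewpoint_depression_850 = 4),
                               trends_per_decade = NULL,
                               noise_sd = NULL,
                               synoptic_share = 0.8,
                               lightning_rate = 0.02,
                               seed = 1L) {
  vars <- c("tmax", "rh", "wind", "rain", "t850", "t700",
            "dewpoint_depression_850")
  fill <- function(x) {
    out <- stats::setNames(numeric(length(vars)), vars)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  means <- fill(means); amplitudes <- fill(amplitudes)
  trends <- fill(trends_per_decade); noise <- fill(noise_sd)
  if (any(noise < 0)) stop("noise SDs must be non-negative")
  if (synoptic_share < 0 || synoptic_share > 1)
    stop("synoptic_share must be in [0, 1]")
  if (lightning_rate < 0 || lightning_rate > 1)
    stop("lightning_rate must be in [0, 1]")
  if (means[["dewpoint_depression_850"]] < 0)
    stop("mean dewpoint depression must be non-negative")
  structure(list(means = means, amplitudes = amplitudes, trends = trends,
                 noise = noise, synoptic_share = synoptic_share,
                 lightning_rate = lightning_rate,
                 seed = as.integer(seed)),
            class = "weather_gen_params")
}

#' Simulate a daily gridded weather cube
#'
#' Generates daily surface and pressure-level fields on a grid over a span
#' of calendar years: seasonal cycle + linear trend + iid Gaussian noise,
#' then physical clamps (RH in [0,100], rain >= 0, Td850 <= T850). With
#' zero noise and zero trend the fields equal the seasonal climatology
#' exactly. Lightning days are iid Bernoulli per pixel-day.
#'
#' @param params a [weather_gen_params()].
#' @param grid a [grid_spec()].
#' @param years integer vector of consecutive calendar years.
#' @return An object of class `weather_cube`: list of arrays
#'   `(n_days, rows, cols)` for `tmax`, `rh`, `wind`, `rain`, `t850`,
#'   `t700`, `td850`, logical `lightning`, plus `dates` and `grid`.
#' @export
simulate_weather <- function(params, grid, years) {
  stopifnot(inherits(params, "weather_gen_params"), is_grid_spec(grid))
  years <- sort(unique(as.integer(years)))
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  # fractional years since record start, for trend injection
  tfrac <- as.numeric(dates - dates[1]) / 365.25
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(params$seed, "weather"))
  npix <- grid$rows * grid$cols
  # peak day-of-year: Jan 15 for thermal variables, Jul 15 for rh/rain
  peak <- c(tmax = 15, rh = 196, wind = 15, rain = 196, t850 = 15,
            t700 = 15, dewpoint_depression_850 = 15)
  make_field <- function(v) {
    clim <- params$means[[v]] + params$amplitudes[[v]] *
      cos(2 * pi * (doy - peak[[v]]) / 365)
    base <- clim + params$trends[[v]] * tfrac / 10
    f <- array(rep(base, npix), c(nd, grid$rows, grid$cols))
    if (params$noise[[v]] > 0) {
      s <- params$synoptic_share
      syn <- sqrt(s) * stats::rnorm(nd)           # one draw per day
      loc <- sqrt(1 - s) * stats::rnorm(nd * npix)
      f <- f + params$noise[[v]] *
        (array(rep(syn, npix), c(nd, grid$rows, grid$cols)) +
           array(loc, c(nd, grid$rows, grid$cols)))
    }
    f
  }
  tmax <- make_field("tmax")
  rh <- pmin(pmax(make_field("rh"), 0), 100)
  wind <- pmax(make_field("wind"), 0)
  rain <- pmax(make_field("rain"), 0)
  t850 <- make_field("t850")
  t700 <- make_field("t700")
  dd <- pmax(make_field("dewpoint_depression_850"), 0)
  td850 <- t850 - dd
  set.seed(substream_seed(params$seed, "lightning"))
  lightning <- array(stats::runif(nd * npix) < params$lightning_rate,
                     c(nd, grid$rows, grid$cols))
  structure(list(tmax = tmax, rh = rh, wind = wind, rain = rain,
                 t850 = t850, t700 = t700, td850 = td850,
                 lightning = lightning, dates = dates, grid = grid),
            class = "weather_cube")
}

#' @export
print.weather_cube <- function(x, ...) {
  cat(sprintf("weather_cube: %d days (%s to %s) on a %d x %d grid\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$grid$rows, x$grid$cols))
  invisible(x)
}

#' Distribute annual fires into a monthly burned-area product
#'
#' Emulates a satellite monthly burned-area product from an annual fire
#' history: each wildfire pixel-year is dated to one month of its fire
#' year (July of the event's calendar year through the following June),
#' drawn from `month_weights`; a configurable small fraction of burned
#' pixels is additionally flagged as burning a second time in a later
#' month, to exercise the union (not-recounted) accounting.
#'
#' @param history a `fire_history`.
#' @param month_weights numeric vector of length 12 summing to 1; the
#'   within-fire-year month distribution ordered July..June.
#' @param double_burn_frac fraction of burned pixels receiving a second
#'   burn month (default 0).
#' @param seed integer seed.
#' @return An object of class `monthly_burned`: list with logical array
#'   `burned` of dim `(rows, cols, n_months)`, data frame `months`
#'   (calendar `year`, `month`), `grid`, and `source` label.
#' @export
simulate_monthly_burned <- function(history, month_weights = rep(1 / 12, 12),
                                    double_burn_frac = 0, seed = 1L) {
  stopifnot(inherits(history, "fire_history"))
  if (length(month_weights) != 12L || any(month_weights < 0) ||
      abs(sum(month_weights) - 1) > 1e-8)
    stop("month_weights must be 12 non-negative values summing to 1")
  if (double_burn_frac < 0 || double_burn_frac > 1)
    stop("double_burn_frac must be in [0, 1]")
  g <- history$grid
  years <- history$years
  # month axis: July of first year .. June of (last year + 1)
  cal <- do.call(rbind, lapply(years, function(y)
    data.frame(year = c(rep(y, 6), rep(y + 1L, 6)), month = c(7:12, 1:6))))
  nm <- nrow(cal)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, "monthly"))
  burned <- array(FALSE, c(g$rows, g$cols, nm))
  for (t in seq_along(years)) {
    idx <- which(history$wildfire[, , t])
    if (!length(idx)) next
    mo <- sample.int(12L, length(idx), replace = TRUE, prob = month_weights)
    base <- (t - 1L) * 12L
    for (m in sort(unique(mo))) {
      sl <- burned[, , base + m]
      sl[idx[mo == m]] <- TRUE
      burned[, , base + m] <- sl
    }
    if (double_burn_frac > 0) {
      dbl <- idx[stats::runif(length(idx)) < double_burn_frac & mo < 12L]
      mo2 <- mo[match(dbl, idx)]
      if (length(dbl)) {
        # second burn in a uniformly later month of the same fire year
        m2 <- mo2 + vapply(12L - mo2, function(k) sample.int(k, 1L), 1L)
        for (m in sort(unique(m2))) {
          sl <- burned[, , base + m]
          sl[dbl[m2 == m]] <- TRUE
          burned[, , base + m] <- sl
        }
      }
    }
  }
  structure(list(burned = burned, months = cal, grid = g,
                 source = "synthetic"),
            class = "monthly_burned")
}
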