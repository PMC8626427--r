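#' Configuration for an end-to-end synthetic run
#'
#' Bundles every tunable of the demonstration pipeline: grid size, record
#' span, fire-process and weather parameters, the fire-year start month,
#' index thresholds and epochs, and the single top-level seed from which
#' every generator derives its substream. The config round-trips
#' losslessly through [write_run_config()]/[read_run_config()].
#'
#' @param rows,cols analysis grid size.
#' @param start_year,end_year record span for the fire history.
#' @param fire_p annual wildfire probability.
#' @param prescribed_mean_km2,prescribed_sd_km2 prescribed-burn layer.
#' @param weather_years span of the daily weather record.
#' @param tmax_trend_per_decade injected Tmax trend (deg C / decade).
#' @param noise_sd daily Gaussian noise SD applied to every weather
#'   variable.
#' @param ffdi_thresholds inclusive FFDI day-count thresholds.
#' @param dry_lightning_mm dry-lightning rainfall threshold.
#' @param megafire_km2 megafire absolute threshold.
#' @param epoch1,epoch2 epoch-change calendar-year ranges.
#' @param seed top-level integer seed.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(rows = 40, cols = 40, start_year = 1930,
                       end_year = 2019, fire_p = 0.05,
                       prescribed_mean_km2 = 30, prescribed_sd_km2 = 8,
                       weather_years = 1980:2019,
                       tmax_trend_per_decade = 0.3, noise_sd = 1.5,
                       ffdi_thresholds = c(25, 50),
                       dry_lightning_mm = 2.5, megafire_km2 = 10000,
                       epoch1 = c(1980, 1999), epoch2 = c(2000, 2019),
                       seed = 1L) {
  if (any(c(ffdi_thresholds, dry_lightning_mm, megafire_km2) <= 0))
    stop("all thresholds must be positive")
  if (epoch1[2] >= epoch2[1]) stop("epochs must not overlap")
  structure(list(rows = rows, cols = cols, start_year = start_year,
                 end_year = end_year, fire_p = fire_p,
                 prescribed_mean_km2 = prescribed_mean_km2,
                 prescribed_sd_km2 = prescribed_sd_km2,
                 weather_years = weather_years,
                 tmax_trend_per_decade = tmax_trend_per_decade,
                 noise_sd = noise_sd, ffdi_thresholds = ffdi_thresholds,
                 dry_lightning_mm = dry_lightning_mm,
                 megafire_km2 = megafire_km2, epoch1 = epoch1,
                 epoch2 = epoch2, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path for the plain-text key-value config.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k)
    sprintf("%s: %s", k, paste(format(config[[k]], digits = 17),
                               collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], " ", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(run_config, vals)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a fire history and weather record from a [run_config()],
#' then runs every analysis stage: monthly burned-area aggregation to
#' fire years and seasons, cause-split series, megafire years, YSLF
#' reconstruction with decadal summaries, fire-weather indices with
#' FFDI day counts and epoch changes, and the trend/regression layer.
#' Deterministic for a fixed config: the same config and seed give
#' byte-identical output tables.
#'
#' @param config a `run_config`.
#' @param out_dir optional directory; if supplied, every table is written
#'   as CSV together with a manifest of the parameters.
#' @return A report bundle (list of tables and fits); see
#'   [render_report()].
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  grid <- grid_spec(config$rows, config$cols, origin_lat = -33,
                    origin_lon = 146, cellsize = 0.01)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  history <- stage("simulate-fire-history", {
    params <- fire_process_params(grid, config$start_year, config$end_year,
                                  p = config$fire_p,
                                  prescribed_mean_km2 = config$prescribed_mean_km2,
                                  prescribed_sd_km2 = config$prescribed_sd_km2,
                                  seed = substream_seed(config$seed, "history"))
    simulate_fire_history(params)
  })
  # month weights ordered July..June, peaking in the austral summer
  monthly <- stage("simulate-monthly-burned",
    simulate_monthly_burned(history,
                            month_weights = c(0.01, 0.01, 0.05, 0.08, 0.11,
                                              0.25, 0.25, 0.16, 0.04, 0.02,
                                              0.01, 0.01),
                            double_burn_frac = 0.01,
                            seed = substream_seed(config$seed, "monthly")))
  areas <- cell_area_km2(grid)
  annual <- stage("burned-area",
    fire_year_burned_area(monthly, areas = areas, keep_partial = TRUE))
  cause <- stage("cause-split", split_by_cause(history, areas = areas))
  mega <- stage("megafire", megafire_years(annual,
                                           threshold_km2 = config$megafire_km2))
  yg <- stage("yslf", yslf_reconstruct(history,
                                       seed = substream_seed(config$seed, "yslf")))
  dec_starts <- seq(config$end_year - 39, config$end_year - 9, by = 10)
  dec_starts <- dec_starts[dec_starts >= config$start_year]
  decadal <- stage("yslf-decades", {
    if (!length(dec_starts))
      stop("record too short for any decadal summary")
    do.call(rbind, lapply(dec_starts,
    function(d0) {
      s <- decadal_summary(yg, d0)
      data.frame(decade = s$decade, mean_yslf = s$mean, sd_yslf = s$sd)
    }))
  })
  wx <- stage("simulate-weather", {
    wgrid <- grid_spec(6, 6, origin_lat = -33, origin_lon = 146,
                       cellsize = 0.1)
    wp <- weather_gen_params(
      trends_per_decade = c(tmax = config$tmax_trend_per_decade),
      noise_sd = c(tmax = config$noise_sd, rh = config$noise_sd * 4,
                   wind = config$noise_sd * 2, rain = config$noise_sd * 3,
                   t850 = config$noise_sd, t700 = config$noise_sd,
                   dewpoint_depression_850 = config$noise_sd),
      seed = substream_seed(config$seed, "wx"))
    simulate_weather(wp, wgrid, config$weather_years)
  })
  idx <- stage("fire-weather", fire_weather_indices(wx))
  day_counts <- stage("ffdi-days", {
    do.call(rbind, lapply(config$ffdi_thresholds, function(th) {
      d <- days_over_threshold(idx$ffdi, idx$dates, threshold = th)
      d$threshold <- th
      d
    }))
  })
  epochs <- stage("epoch-change", {
    ff <- epoch_change(idx$ffdi, idx$dates, config$epoch1, config$epoch2)
    tm <- epoch_change(wx$tmax, wx$dates, config$epoch1, config$epoch2)
    dl <- epoch_change(idx$dry_lightning, idx$dates, config$epoch1,
                       c(config$epoch2[1],
                         min(config$epoch2[2], 2016)))
    data.frame(variable = c("ffdi", "tmax", "dry_lightning"),
               mean_change = c(mean(ff$change), mean(tm$change),
                               mean(dl$change)),
               percent_change = c(NA, NA, mean(dl$percent_change)))
  })
  trends <- stage("trends", {
    lin <- fit_linear(annual)
    exp_fit <- fit_exponential(annual)
    cool <- data.frame(fire_year = annual$fire_year,
                       value = annual$area_autumn_km2 + annual$area_winter_km2)
    cool_fit <- if (all(cool$value > 0)) fit_exponential(cool) else NULL
    d25 <- day_counts[day_counts$threshold == config$ffdi_thresholds[1],
                      c("fire_year", "days")]
    common <- intersect(annual$fire_year, d25$fire_year)
    bvf <- if (length(common) >= 3 &&
               length(unique(d25$days[d25$fire_year %in% common])) > 1)
      fit_burned_vs_ffdi(annual[annual$fire_year %in% common, ],
                         d25[d25$fire_year %in% common, ]) else NULL
    list(linear = lin, exponential = exp_fit, cool_season = cool_fit,
         burned_vs_ffdi25 = bvf)
  })
  bundle <- list(config = config, annual = annual, cause = cause,
                 megafire = mega, yslf_decadal = decadal,
                 ffdi_days = day_counts, epoch_changes = epochs,
                 trends = trends,
                 reference = list(
                   consensus_2019 = consensus_2019_burned_area(),
                   prescribed_pct = prescribed_burn_fraction_pct()))
  class(bundle) <- "fire_report_bundle"
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(bundle$annual, "burned_area_fire_year")
  wr(bundle$cause, "burned_area_by_cause")
  wr(bundle$yslf_decadal, "yslf_decadal")
  wr(bundle$ffdi_days, "ffdi_day_counts")
  wr(bundle$epoch_changes, "epoch_changes")
  cfg <- bundle$config
  manifest <- c(sprintf("generated: run_config seed %d", cfg$seed),
                vapply(names(unclass(cfg)), function(k)
                  sprintf("%s: %s", k,
                          paste(format(cfg[[k]]), collapse = " ")), ""))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Render a report bundle as printed tables
#'
#' Prints the fire-year burned-area table, cause split, megafire years,
#' YSLF decadal summary, FFDI day-count series, epoch-change summary and
#' the trend fits of a [run_pipeline()] bundle.
#'
#' @param bundle a `fire_report_bundle`.
#' @return The bundle, invisibly.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "fire_report_bundle"))
  need <- c("annual", "cause", "megafire", "yslf_decadal", "ffdi_days",
            "epoch_changes", "trends")
  missing <- setdiff(need, names(bundle))
  if (length(missing))
    stop(sprintf("incomplete bundle; missing: %s",
                 paste(missing, collapse = ", ")))
  cat("== Burned area by fire year (km^2) ==\n")
  print(utils::head(bundle$annual, 5))
  cat(sprintf("   ... %d fire years, total %.0f km^2\n\n",
              nrow(bundle$annual), sum(bundle$annual$area_km2)))
  cat("== Megafire years ==\n")
  cat(sprintf("  over threshold: %s\n  top decile:     %s\n\n",
              paste(bundle$megafire$over_threshold, collapse = ", "),
              paste(bundle$megafire$top_percentile, collapse = ", ")))
  cat("== YSLF decadal means ==\n")
  print(bundle$yslf_decadal)
  cat("\n== FFDI day counts (head) ==\n")
  print(utils::head(bundle$ffdi_days, 5))
  cat("\n== Epoch changes ==\n")
  print(bundle$epoch_changes)
  cat("\n== Trend fits ==\n")
  print(bundle$trends$linear)
  print(bundle$trends$exponential)
  if (!is.null(bundle$trends$burned_vs_ffdi25)) {
    print(bundle$trends$burned_vs_ffdi25)
    cat(sprintf("  burned-area multiplier per extra FFDI>=25 day: %.3f (%.1f%%)\n",
                bundle$trends$burned_vs_ffdi25$multiplier_per_day,
                bundle$trends$burned_vs_ffdi25$percent_per_day))
  }
  cat(sprintf("\n== Published reference figures ==\n  2019 consensus burned area: %.0f +/- %.0f km^2\n  prescribed burning: %.2f%% of forest area per year\n",
              bundle$reference$consensus_2019$mean_km2,
              bundle$reference$consensus_2019$sd_km2,
              bundle$reference$prescribed_pct))
  invisible(bundle)
}
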