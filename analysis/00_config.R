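# Shared configuration for the analysis scripts. Every script sources
# this file and regenerates its (deterministic, seeded) inputs through
# the package, so each can be run standalone, in order, from the
# repository root:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_burned_area.R
#   ...
#
# Outputs land under results/.

library(firetrends)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

CFG <- run_config(
  rows = 60, cols = 60,            # 60 x 60 analysis grid at 0.01 deg
  start_year = 1930, end_year = 2019,
  fire_p = 0.05,                   # mean fire return interval ~20 years
  prescribed_mean_km2 = 40, prescribed_sd_km2 = 10,
  weather_years = 1980:2019,
  tmax_trend_per_decade = 0.3,     # injected warming trend
  noise_sd = 1.5,
  seed = 20260925L
)

GRID <- grid_spec(CFG$rows, CFG$cols, origin_lat = -33, origin_lon = 146,
                  cellsize = 0.01)

make_history <- function() {
  simulate_fire_history(fire_process_params(
    GRID, CFG$start_year, CFG$end_year, p = CFG$fire_p,
    prescribed_mean_km2 = CFG$prescribed_mean_km2,
    prescribed_sd_km2 = CFG$prescribed_sd_km2,
    seed = CFG$seed))
}

make_monthly <- function(history) {
  # month weights (ordered July..June) peak in the austral summer:
  # roughly 66% summer, 24% spring, 7% autumn, 3% winter
  simulate_monthly_burned(history,
                          month_weights = c(0.01, 0.01, 0.05, 0.08, 0.11,
                                            0.25, 0.25, 0.16, 0.04, 0.02,
                                            0.01, 0.01),
                          double_burn_frac = 0.01, seed = CFG$seed + 1L)
}

make_weather <- function() {
  wgrid <- grid_spec(6, 6, origin_lat = -33, origin_lon = 146,
                     cellsize = 0.1)
  # a dry temperate fire climate: hot, dry, windy summers so that Very
  # High (FFDI >= 25) fire-danger days occur a handful of times a year
  wp <- weather_gen_params(
    means = c(tmax = 24, rh = 40, wind = 25, rain = 1.2, t850 = 14,
              t700 = 4, dewpoint_depression_850 = 12),
    amplitudes = c(tmax = 11, rh = -20, wind = 5, rain = -0.8, t850 = 7,
                   t700 = 6, dewpoint_depression_850 = 7),
    trends_per_decade = c(tmax = CFG$tmax_trend_per_decade),
    noise_sd = c(tmax = 4.5, rh = 12, wind = 10, rain = 3.5, t850 = 2.5,
                 t700 = 2.5, dewpoint_depression_850 = 4),
    lightning_rate = 0.02, seed = CFG$seed + 2L)
  list(cube = simulate_weather(wp, wgrid, CFG$weather_years), grid = wgrid)
}
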