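#' Published national reference figures
#'
#' Small bundled tables of published Australian forest-fire reference
#' figures used by the reporting layer: the three independent
#' burned-area estimates for the 2019 fire year (July 2019 - June 2020)
#' from the agency rapid-assessment dataset (NIAFED), the AVHRR-Landgate
#' satellite product and the NASA-MODIS product; and the national forest
#' study area with the mean annual prescribed-burn area.
#'
#' @return `reference_2019_estimates()`: data frame `product`,
#'   `area_km2`; `reference_forest_figures()`: data frame `quantity`,
#'   `value`, `units`.
#' @export
reference_2019_estimates <- function() {
  utils::read.csv(system.file("extdata", "burned_area_2019_products.csv",
                              package = "firetrends"))
}

#' @rdname reference_2019_estimates
#' @export
reference_forest_figures <- function() {
  utils::read.csv(system.file("extdata", "forest_reference.csv",
                              package = "firetrends"))
}

#' Consensus 2019 burned-area estimate
#'
#' Mean and SD of the three independent 2019 fire-year burned-area
#' products.
#'
#' @param estimates data frame with an `area_km2` column (default the
#'   bundled table).
#' @return List: `mean_km2`, `sd_km2`, `n`.
#' @export
consensus_2019_burned_area <- function(estimates = reference_2019_estimates()) {
  list(mean_km2 = mean(estimates$area_km2),
       sd_km2 = stats::sd(estimates$area_km2),
       n = nrow(estimates))
}

#' Prescribed burning as a share of the forest estate
#'
#' Mean annual prescribed-burn area divided by the forest study area, in
#' percent. On the bundled national figures this is just under 1% per
#' year.
#'
#' @param figures data frame as returned by
#'   [reference_forest_figures()].
#' @return Percent of forest area treated per year (scalar).
#' @export
prescribed_burn_fraction_pct <- function(figures = reference_forest_figures()) {
  get1 <- function(q) figures$value[figures$quantity == q][1]
  100 * get1("prescribed_burn_mean_annual_area") / get1("forest_study_area")
}
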