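#' Fire-year and season assignment
#'
#' Fire years run July to June to span the Austral summer and are labelled
#' by the starting calendar year of July: months 7-12 of calendar year `y`
#' belong to fire year `y`, months 1-6 to fire year `y - 1`. Seasons are
#' the Austral meteorological seasons: DJF summer, MAM autumn, JJA winter,
#' SON spring, so autumn + winter is March-August (the cool season).
#'
#' @param year calendar year (integer vector).
#' @param month calendar month, 1-12 (integer vector).
#' @return `assign_fire_year`: integer fire-year label;
#'   `assign_season`: character season label.
#' @examples
#' assign_fire_year(2019, 7)  # 2019
#' assign_fire_year(2020, 6)  # 2019
#' assign_season(3)           # "autumn"
#' @export
assign_fire_year <- function(year, month) {
  month <- as.integer(month)
  if (anyNA(month) || any(month < 1L | month > 12L))
    stop("month must be in 1..12")
  as.integer(year) - as.integer(month <= 6L)
}

#' @rdname assign_fire_year
#' @export
assign_season <- function(month) {
  month <- as.integer(month)
  if (anyNA(month) || any(month < 1L | month > 12L))
    stop("month must be in 1..12")
  c("summer", "summer", "autumn", "autumn", "autumn", "winter",
    "winter", "winter", "spring", "spring", "spring", "summer")[month]
}

#' Fire-year burned area over a forest mask
#'
#' Aggregates a monthly burned-area product to per-fire-year burned area:
#' the area of the *union* of burned-and-forest cells over the 12 months
#' of each complete fire year. Cells flagged as burning more than once in
#' a fire year are not recounted. Seasonal areas attribute each cell to
#' the season of its first burn month within the fire year, so the four
#' seasonal areas sum exactly to the annual union area.
#'
#' @param monthly a `monthly_burned` object (see
#'   [simulate_monthly_burned()]), or any list with logical array `burned`
#'   `(rows, cols, n_months)` and data frame `months` (`year`, `month`).
#' @param mask logical forest mask matrix on the same grid (default: all
#'   cells included).
#' @param areas cell-area matrix in km^2 (default [cell_area_km2()] of the
#'   product grid).
#' @param keep_partial keep incomplete leading/trailing fire years instead
#'   of erroring (default FALSE: incomplete years are an error).
#' @return Data frame: `fire_year`, `area_km2`, and one
#'   `area_<season>_km2` column per season.
#' @export
fire_year_burned_area <- function(monthly, mask = NULL, areas = NULL,
                                  keep_partial = FALSE) {
  stopifnot(is.list(monthly), !is.null(monthly$burned),
            !is.null(monthly$months))
  b <- monthly$burned
  cal <- monthly$months
  if (!is.null(monthly$grid)) {
    if (!is.null(mask) &&
        !all(dim(mask) == c(monthly$grid$rows, monthly$grid$cols)))
      stop("mask grid does not match the burned-area product grid")
    if (is.null(areas)) areas <- cell_area_km2(monthly$grid)
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(b)[1], dim(b)[2])
  if (is.null(areas)) stop("cell areas required when the product has no grid")
  if (!all(dim(areas) == dim(mask))) stop("areas grid does not match mask")
  fy <- assign_fire_year(cal$year, cal$month)
  seasons <- c("summer", "autumn", "winter", "spring")
  out <- list()
  for (y in sort(unique(fy))) {
    sel <- which(fy == y)
    if (length(sel) != 12L) {
      if (!keep_partial)
        stop(sprintf("fire year %d has %d months, not 12; pass keep_partial = TRUE to keep it",
                     y, length(sel)))
    }
    sel <- sel[order(cal$year[sel] * 100L + cal$month[sel])]
    # month index (within fire year) of each cell's first burn, 0 = unburned
    first <- matrix(0L, dim(b)[1], dim(b)[2])
    for (k in rev(seq_along(sel))) first[b[, , sel[k]]] <- k
    first[!mask] <- 0L
    union_area <- sum(areas[first > 0L])
    row <- data.frame(fire_year = y, area_km2 = union_area)
    seas_of <- assign_season(cal$month[sel])
    for (s in seasons) {
      in_s <- first > 0L & seas_of[pmax(first, 1L)] == s
      row[[paste0("area_", s, "_km2")]] <- sum(areas[in_s])
    }
    out[[as.character(y)]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split an annual fire history by cause
#'
#' Separates wildfire and prescribed-burn pixel-events into two annual
#' count series; the two series always sum to the unsplit total.
#'
#' @param history a `fire_history`.
#' @param mask optional logical mask restricting the count.
#' @param areas optional cell-area matrix (km^2); if supplied, areas are
#'   reported instead of pixel counts.
#' @return Data frame: `year`, `wildfire`, `prescribed`, `total`.
#' @export
split_by_cause <- function(history, mask = NULL, areas = NULL) {
  stopifnot(inherits(history, "fire_history"))
  if (is.null(history$prescribed)) stop("history carries no cause attribute")
  g <- history$grid
  if (is.null(mask)) mask <- matrix(TRUE, g$rows, g$cols)
  w <- if (is.null(areas)) (mask + 0) else areas * mask
  ny <- length(history$years)
  wf <- vapply(seq_len(ny), function(t) sum(w[history$wildfire[, , t]]), 0)
  pb <- vapply(seq_len(ny), function(t) sum(w[history$prescribed[, , t]]), 0)
  data.frame(year = history$years, wildfire = wf, prescribed = pb,
             total = wf + pb)
}

#' Identify megafire years
#'
#' A megafire year is a fire year with exceptionally large burned area.
#' Two definitions are reported separately: (i) years whose burned area
#' exceeds an absolute threshold (default 10,000 km^2 = 1 Mha), and (ii)
#' years at or above a percentile of the series (default the top decile).
#' With the percentile rule, all years tied at the cutoff value are
#' returned.
#'
#' @param series data frame with `fire_year` and `area_km2` (or a numeric
#'   vector named by fire year).
#' @param threshold_km2 absolute-area threshold (km^2).
#' @param percentile percentile cutoff in [0, 100].
#' @return List with integer vectors `over_threshold` and
#'   `top_percentile` (fire-year labels), plus the `cutoff_km2` value used
#'   by the percentile rule.
#' @export
megafire_years <- function(series, threshold_km2 = 10000, percentile = 90) {
  if (is.data.frame(series)) {
    yrs <- series$fire_year
    val <- series$area_km2
  } else {
    val <- as.numeric(series)
    yrs <- as.integer(names(series))
  }
  if (!length(val)) stop("series is empty")
  cutoff <- stats::quantile(val, percentile / 100, names = FALSE, type = 7)
  list(over_threshold = yrs[val > threshold_km2],
       top_percentile = yrs[val >= cutoff],
       cutoff_km2 = cutoff)
}

#' Collapse a monthly burned product to annual occurrence
#'
#' A pixel-calendar-year is burned if any of its months burned; used to
#' extend an annual fire-history record with a monthly satellite product.
#'
#' @param monthly a `monthly_burned` object.
#' @return Logical array `(rows, cols, n_years)` with attribute `years`.
#' @export
annualize_monthly <- function(monthly) {
  cal <- monthly$months
  years <- sort(unique(cal$year))
  out <- array(FALSE, c(dim(monthly$burned)[1:2], length(years)))
  for (k in seq_along(years)) {
    sel <- which(cal$year == years[k])
    out[, , k] <- apply(monthly$burned[, , sel, drop = FALSE], c(1, 2), any)
  }
  attr(out, "years") <- years
  out
}
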