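#' Per-pixel mean wildfire frequency
#'
#' The annual wildfire probability `p` of each pixel estimated from its
#' own record: number of record years with a wildfire divided by record
#' length. Prescribed burns are excluded. Only pixels with at least one
#' wildfire in the record are eligible; others return NA.
#'
#' @param history a `fire_history` (wildfire layer used).
#' @return Matrix of `p` (NA on ineligible pixels).
#' @export
estimate_p <- function(history) {
  stopifnot(inherits(history, "fire_history"))
  ny <- length(history$years)
  counts <- apply(history$wildfire, c(1, 2), sum)
  p <- counts / ny
  p[counts == 0L] <- NA_real_
  p
}

#' Geometric-quantile initial years-since-last-fire
#'
#' Inverse-CDF draw assigning an initial years-since-last-fire to pixels
#' whose last pre-record fire date is unknown:
#' `ceil(ln(1 - u) / ln(1 - p))`, with `u ~ Uniform(0, 1)` and `p` the
#' pixel's mean annual wildfire frequency. This is exactly the geometric
#' quantile function on \{1, 2, ...\}: the result `k` has probability
#' `p * (1 - p)^(k - 1)`, the stationary distribution of time since the
#' last event of a Bernoulli(`p`) process conditional on no event in the
#' initialization year. The minimum value is 1, so initializer values
#' never collide with the 0 code reserved for pixels burning in the
#' initialization year.
#'
#' @param u uniform draw(s) in the open interval (0, 1).
#' @param p annual fire frequency(ies) in (0, 1); recycled against `u`.
#' @param rounding bracket convention: `"ceiling"` (default; proper
#'   geometric quantile), `"floor"` or `"round"` for sensitivity checks
#'   (both are floored at 1).
#' @return Integer initial years-since-last-fire, >= 1.
#' @export
geometric_init <- function(u, p, rounding = c("ceiling", "floor", "round")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("u must lie strictly inside (0, 1)")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)")
  raw <- log1p(-u) / log1p(-p)
  k <- switch(rounding, ceiling = ceiling(raw), floor = floor(raw),
              round = round(raw))
  as.integer(pmax(k, 1))
}

#' Reconstruct per-pixel years-since-last-fire surfaces
#'
#' Builds the annual years-since-last-fire (YSLF) stack from an annual
#' wildfire history. Pixels burning in the first record year start at 0;
#' all other eligible pixels (>= 1 wildfire anywhere in the record) start
#' at a [geometric_init()] draw using their own estimated frequency
#' [estimate_p()]. Each subsequent year the surface increments by 1 and
#' resets to 0 wherever a wildfire is recorded. Pixels never burned in
#' the record are masked (NA). The provenance flag of a pixel-year is
#' `"estimated"` until the pixel's first in-record fire, `"observed"`
#' from then on; observed values are seed-independent.
#'
#' @param history a `fire_history` starting at the record origin.
#' @param seed integer seed driving the initializer draws.
#' @param rounding passed to [geometric_init()].
#' @return An object of class `yslf_grid`: list with integer array `yslf`
#'   `(rows, cols, n_years)` (NA outside the eligibility mask), logical
#'   array `estimated` (same shape; TRUE where the value still descends
#'   from the initializer), logical matrix `eligible`, `years`, `grid`,
#'   and the `p` matrix used.
#' @export
yslf_reconstruct <- function(history, seed = 1L,
                             rounding = c("ceiling", "floor", "round")) {
  stopifnot(inherits(history, "fire_history"))
  rounding <- match.arg(rounding)
  years <- history$years
  if (any(diff(years) != 1L)) stop("gap years in the fire-history stack")
  ny <- length(years)
  g <- history$grid
  p <- estimate_p(history)
  eligible <- !is.na(p)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, "yslf-init"))
  yslf <- array(NA_integer_, c(g$rows, g$cols, ny))
  est <- array(FALSE, c(g$rows, g$cols, ny))
  burn1 <- history$wildfire[, , 1]
  y0 <- matrix(NA_integer_, g$rows, g$cols)
  y0[eligible & burn1] <- 0L
  need_init <- eligible & !burn1
  # p < 1 is guaranteed here: p = 1 implies a fire in every year incl. year 1
  u <- stats::runif(sum(need_init))
  y0[need_init] <- geometric_init(u, p[need_init], rounding = rounding)
  yslf[, , 1] <- y0
  e0 <- matrix(FALSE, g$rows, g$cols)
  e0[need_init] <- TRUE
  est[, , 1] <- e0
  prev <- y0
  eprev <- e0
  for (t in seq_len(ny)[-1]) {
    burn <- history$wildfire[, , t]
    cur <- prev + 1L
    cur[eligible & burn] <- 0L
    yslf[, , t] <- cur
    ecur <- eprev & !burn
    est[, , t] <- ecur
    prev <- cur
    eprev <- ecur
  }
  structure(list(yslf = yslf, estimated = est, eligible = eligible,
                 years = years, grid = g, p = p),
            class = "yslf_grid")
}

#' @export
print.yslf_grid <- function(x, ...) {
  ny <- length(x$years)
  cat(sprintf("yslf_grid: years %d-%d, %d eligible of %d pixels, %.1f%% of final-year values observed\n",
              x$years[1], x$years[ny], sum(x$eligible), length(x$eligible),
              100 * (1 - sum(x$estimated[, , ny]) / max(1, sum(x$eligible)))))
  invisible(x)
}

#' Annual spatial mean years-since-last-fire
#'
#' Spatial mean of the YSLF surface over eligible pixels (optionally
#' restricted by a forest mask and/or area-weighted) for each record
#' year.
#'
#' @param yg a `yslf_grid`.
#' @param mask optional logical mask intersected with the eligibility
#'   mask.
#' @param areas optional cell-area matrix for area weighting; default
#'   unweighted pixel counts.
#' @return Data frame: `year`, `mean_yslf`.
#' @export
yslf_annual_means <- function(yg, mask = NULL, areas = NULL) {
  stopifnot(inherits(yg, "yslf_grid"))
  sel <- yg$eligible
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("no eligible pixels under the supplied mask")
  w <- if (is.null(areas)) (sel + 0) else areas * sel
  wsum <- sum(w)
  means <- vapply(seq_along(yg$years),
                  function(t) sum(w * yg$yslf[, , t], na.rm = TRUE) / wsum,
                  0)
  data.frame(year = yg$years, mean_yslf = means)
}

#' Decadal mean and SD of years-since-last-fire
#'
#' For each year of a decade, computes the spatial mean YSLF over
#' eligible pixels; the decadal statistics are the mean and SD of those
#' (up to 10) annual spatial means. Set `pixel_sd = TRUE` to instead
#' report the SD across pixels of the decade-mean pixel values.
#'
#' @param yg a `yslf_grid`.
#' @param decade_start first calendar year of the decade (e.g. 2010).
#' @param mask,areas passed to [yslf_annual_means()].
#' @param pixel_sd report across-pixel SD instead of across-year SD.
#' @return List: `decade`, `mean`, `sd`, `n_years`.
#' @export
decadal_summary <- function(yg, decade_start, mask = NULL, areas = NULL,
                            pixel_sd = FALSE) {
  stopifnot(inherits(yg, "yslf_grid"))
  yrs <- decade_start:(decade_start + 9L)
  keep <- yrs %in% yg$years
  if (!any(keep)) stop("decade lies outside the record")
  yrs <- yrs[keep]
  am <- yslf_annual_means(yg, mask = mask, areas = areas)
  vals <- am$mean_yslf[am$year %in% yrs]
  if (pixel_sd) {
    sel <- yg$eligible
    if (!is.null(mask)) sel <- sel & mask
    idx <- which(yg$years %in% yrs)
    pixmean <- apply(yg$yslf[, , idx, drop = FALSE], c(1, 2), mean)
    sdv <- stats::sd(pixmean[sel])
  } else {
    sdv <- stats::sd(vals)
  }
  list(decade = paste0(yrs[1], "s"), mean = mean(vals), sd = sdv,
       n_years = length(yrs))
}

#' Burned-at-least-once fraction by vegetation class
#'
#' Fraction of each class's pixels that recorded at least one wildfire
#' over the record; with `areas` supplied the fraction is area-weighted.
#' For a stationary Bernoulli(p) process over n years the expected
#' fraction is `1 - (1 - p)^n`.
#'
#' @param history a `fire_history`.
#' @param classes matrix of class labels (character/factor/integer)
#'   aligned with the history grid; NA cells are excluded.
#' @param areas optional cell-area matrix.
#' @return Data frame: `class`, `n_pixels`, `burned_fraction`.
#' @export
burned_fraction_by_class <- function(history, classes, areas = NULL) {
  stopifnot(inherits(history, "fire_history"))
  g <- history$grid
  if (!all(dim(classes) == c(g$rows, g$cols)))
    stop("class raster is not aligned with the fire-history grid")
  ever <- apply(history$wildfire, c(1, 2), any)
  w <- if (is.null(areas)) matrix(1, g$rows, g$cols) else areas
  keep <- !is.na(classes)
  cl <- as.character(classes[keep])
  burned_w <- tapply(w[keep] * ever[keep], cl, sum)
  total_w <- tapply(w[keep], cl, sum)
  npix <- tapply(rep(1L, sum(keep)), cl, sum)
  data.frame(class = names(total_w), n_pixels = as.integer(npix),
             burned_fraction = as.numeric(burned_w / total_w),
             row.names = NULL)
}
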