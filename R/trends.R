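#' Linear and log-linear trend fits for fire-year series
#'
#' `fit_linear` regresses the series value on fire year by ordinary least
#' squares; `fit_exponential` regresses the natural log of the value, so
#' the trend is a constant multiplicative growth rate
#' `exp(slope) - 1` per year. Both centre the year index internally for
#' conditioning and back-transform the intercept to calendar years, and
#' report the classical two-sided t-test on the slope. Non-positive
#' values cannot enter a log fit and are excluded with a message (their
#' count is recorded in the result).
#'
#' @param series data frame with a year column (`fire_year` or `year`)
#'   and a value column (`value`, `area_km2` or `days`), or a numeric
#'   vector with years as names.
#' @param robust_se use a heteroskedasticity/autocorrelation-robust
#'   (Newey-West style, lag 1) slope standard error instead of the
#'   classical one. Off by default.
#' @return An object of class `trend_fit`: list with `model`
#'   (`"linear"` or `"log-linear"`), `intercept`, `slope`, `growth_rate`
#'   (log-linear only), `p_value`, `r_squared`, `n`, `n_excluded`,
#'   `residuals`, `fitted`, `x_range` and a `predict(x)` closure on the
#'   response scale.
#' @export
fit_linear <- function(series, robust_se = FALSE) {
  d <- as_year_value(series)
  if (nrow(d) < 3L) stop("need at least 3 points for a trend fit")
  if (length(unique(d$year)) < 2L) stop("year values are constant")
  trend_ols(d$year, d$value, log_response = FALSE, robust_se = robust_se,
            n_excluded = 0L)
}

#' @rdname fit_linear
#' @export
fit_exponential <- function(series, robust_se = FALSE) {
  d <- as_year_value(series)
  bad <- d$value <= 0
  if (any(bad)) {
    message(sprintf("excluding %d non-positive value(s) from the log fit",
                    sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) < 3L) stop("need at least 3 positive points for a log fit")
  if (length(unique(d$year)) < 2L) stop("year values are constant")
  trend_ols(d$year, log(d$value), log_response = TRUE,
            robust_se = robust_se, n_excluded = sum(bad))
}

as_year_value <- function(series) {
  if (is.data.frame(series)) {
    ycol <- intersect(c("fire_year", "year"), names(series))[1]
    vcol <- intersect(c("value", "area_km2", "days"), names(series))[1]
    if (is.na(ycol) || is.na(vcol))
      stop("series needs a year column (fire_year/year) and a value column (value/area_km2/days)")
    data.frame(year = as.numeric(series[[ycol]]),
               value = as.numeric(series[[vcol]]))
  } else {
    if (is.null(names(series))) stop("vector series must be named by year")
    data.frame(year = as.numeric(names(series)),
               value = as.numeric(series))
  }
}

trend_ols <- function(x, y, log_response, robust_se, n_excluded,
                      predictor = "year") {
  xc <- x - mean(x)
  fit <- stats::lm(y ~ xc)
  # "essentially perfect fit" warnings are expected when validating on
  # noiseless inputs
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]] - slope * mean(x)
  # a numerically constant response carries no trend evidence at all
  if (stats::sd(y) <= 1e-12 * (abs(mean(y)) + 1)) {
    slope <- 0
    intercept <- mean(y)
    fit <- stats::lm(I(rep(mean(y), length(y))) ~ xc)
    sm$coefficients[2, 4] <- 1
    sm$r.squared <- 0
  }
  if (robust_se) {
    se <- newey_west_se(xc, stats::residuals(fit))
    tval <- slope / se
    pval <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
  } else {
    pval <- sm$coefficients[2, 4]
  }
  # degenerate residual variance: a zero slope carries no evidence (p = 1),
  # an exactly recovered nonzero slope is certain (p = 0)
  if (!is.finite(pval))
    pval <- if (abs(slope) < sqrt(.Machine$double.eps)) 1 else 0
  res <- list(model = if (log_response) "log-linear" else "linear",
              predictor = predictor,
              intercept = intercept, slope = slope,
              growth_rate = if (log_response) exp(slope) - 1 else NULL,
              p_value = pval, r_squared = sm$r.squared,
              n = length(y), n_excluded = n_excluded,
              residuals = unname(stats::residuals(fit)),
              fitted = if (log_response) exp(unname(stats::fitted(fit)))
                       else unname(stats::fitted(fit)),
              x_range = range(x))
  res$predict <- function(xnew) {
    eta <- intercept + slope * xnew
    if (log_response) exp(eta) else eta
  }
  class(res) <- "trend_fit"
  res
}

# Newey-West (lag-1 Bartlett) standard error of the slope in simple OLS
newey_west_se <- function(xc, e, lag = 1L) {
  n <- length(e)
  sxx <- sum(xc^2)
  v <- sum(xc^2 * e^2)
  for (l in seq_len(lag)) {
    w <- 1 - l / (lag + 1)
    v <- v + 2 * w * sum(xc[-seq_len(l)] * e[-seq_len(l)] *
                           xc[seq_len(n - l)] * e[seq_len(n - l)])
  }
  sqrt(v) / sxx
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("%s trend fit (n = %d%s)\n", x$model, x$n,
              if (x$n_excluded > 0)
                sprintf(", %d non-positive excluded", x$n_excluded) else ""))
  cat(sprintf("  slope = %.6g per %s (p = %.3g), R^2 = %.3f\n",
              x$slope, x$predictor, x$p_value, x$r_squared))
  if (!is.null(x$growth_rate))
    cat(sprintf("  growth rate = %.2f%% per %s\n", 100 * x$growth_rate,
                x$predictor))
  invisible(x)
}

#' Percent change in mean between the two halves of a record
#'
#' `100 * (mean(second half) / mean(first half) - 1)`: the first half is
#' all years strictly before `split_year`, the second half all years at
#' or after it. A value of 350 means the second-half annual average is
#' 4.5 times the first-half average; 500 is a five-fold increase.
#'
#' @param series as in [fit_linear()].
#' @param split_year first year of the second half.
#' @return Percent change (scalar).
#' @export
percent_change_halves <- function(series, split_year) {
  d <- as_year_value(series)
  first <- d$value[d$year < split_year]
  second <- d$value[d$year >= split_year]
  if (!length(first) || !length(second))
    stop("both halves must contain at least one year")
  m1 <- mean(first)
  if (m1 <= 0) stop("first-half mean must be positive")
  100 * (mean(second) / m1 - 1)
}

#' Exponential regression of burned area on fire-weather day counts
#'
#' OLS of `ln(area)` on the annual count of days at or above an FFDI
#' threshold. The slope `b` converts to a multiplicative effect
#' `exp(b)` per additional threshold day, reported as
#' `percent_per_day = 100 * (exp(b) - 1)`.
#'
#' @param burned data frame with `fire_year` and `area_km2` (or `value`).
#' @param days data frame with `fire_year` and `days` (or `value`).
#' @param robust_se as in [fit_linear()].
#' @return A `trend_fit` (predictor = `"day"`) with extra fields
#'   `multiplier_per_day` and `percent_per_day`.
#' @export
fit_burned_vs_ffdi <- function(burned, days, robust_se = FALSE) {
  b <- as_year_value(burned)
  d <- as_year_value(days)
  common <- intersect(b$year, d$year)
  if (length(common) != nrow(b) || length(common) != nrow(d))
    stop("burned-area and day-count series cover different fire years")
  b <- b[match(common, b$year), ]
  d <- d[match(common, d$year), ]
  if (any(b$value <= 0)) stop("burned area must be positive for the log fit")
  if (length(unique(d$value)) < 2L) stop("day-count predictor is constant")
  fit <- trend_ols(d$value, log(b$value), log_response = TRUE,
                   robust_se = robust_se, n_excluded = 0L,
                   predictor = "day")
  fit$multiplier_per_day <- exp(fit$slope)
  fit$percent_per_day <- 100 * (fit$multiplier_per_day - 1)
  fit
}

#' Multivariate regression of log burned area on fire-weather factors
#'
#' OLS of `ln(area)` on a set of fire-weather predictors (FFDI threshold
#' day counts, C-Haines summary, dry-lightning days, ...). Reports the
#' R^2 of the model using the first predictor alone and the increment in
#' R^2 as each further predictor is added in order, plus the pairwise
#' predictor correlations (the usual reason added predictors contribute
#' little is their collinearity with the first).
#'
#' @param area data frame with `fire_year` and `area_km2`/`value`.
#' @param predictors named list of data frames (each with `fire_year`
#'   and a value column); order defines the sequential R^2 decomposition.
#' @return List: `fit` (the full `lm`), `r2_first`, `delta_r2` (named),
#'   `r2_full`, `correlations` (predictor correlation matrix),
#'   `coefficients`, `n`.
#' @export
fit_multivariate <- function(area, predictors) {
  if (!length(predictors)) stop("need at least one predictor")
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be a named list")
  a <- as_year_value(area)
  X <- lapply(predictors, as_year_value)
  years <- Reduce(intersect, c(list(a$year), lapply(X, `[[`, "year")))
  if (length(years) <= length(predictors) + 1L)
    stop("not enough overlapping fire years for the model size")
  if (any(is.na(a$value)) || any(vapply(X, function(d) anyNA(d$value), TRUE)))
    stop("missing values in the regression inputs")
  df <- data.frame(log_area = log(a$value[match(years, a$year)]))
  for (nm in names(X)) df[[nm]] <- X[[nm]]$value[match(years, X[[nm]]$year)]
  M <- as.matrix(df[names(X)])
  qrM <- qr(cbind(1, M))
  if (qrM$rank < ncol(M) + 1L) {
    drop_idx <- setdiff(seq_len(ncol(M) + 1L), qrM$pivot[seq_len(qrM$rank)])
    stop(sprintf("rank-deficient design; collinear predictor(s): %s",
                 paste(colnames(M)[drop_idx - 1L], collapse = ", ")))
  }
  r2 <- numeric(length(X))
  for (k in seq_along(X)) {
    f <- stats::lm(stats::reformulate(names(X)[seq_len(k)], "log_area"),
                   data = df)
    r2[k] <- suppressWarnings(summary(f))$r.squared
  }
  full <- stats::lm(stats::reformulate(names(X), "log_area"), data = df)
  corr <- if (ncol(M) > 1L) stats::cor(M) else matrix(1, 1, 1,
                                                      dimnames = list(names(X), names(X)))
  list(fit = full,
       r2_first = r2[1],
       delta_r2 = stats::setNames(diff(c(0, r2))[-1],
                                  names(X)[-1]),
       r2_full = r2[length(r2)],
       correlations = corr,
       coefficients = stats::coef(full),
       n = length(years))
}

#' Predict burned area from a fitted log-linear model
#'
#' Point prediction on the response scale, `exp(a + b x)` for a
#' log-linear fit (no lognormal bias correction by default; with
#' `bias_correct = TRUE` the prediction is multiplied by
#' `exp(sigma^2 / 2)`). Predictor values beyond the fitted range times
#' the guard factor trigger a warning, not an error — predicting an
#' extreme season from a model fitted to ordinary ones is an
#' extrapolation by construction.
#'
#' @param fit a `trend_fit`.
#' @param x predictor value(s) on the fitted predictor's scale.
#' @param guard extrapolation guard: warn when `x` lies outside the
#'   fitted range expanded by this fraction of its width (default 0.0,
#'   i.e. warn outside the observed range).
#' @param bias_correct apply the lognormal mean correction.
#' @return Predicted value(s) on the response scale.
#' @export
predict_held_out <- function(fit, x, guard = 0, bias_correct = FALSE) {
  stopifnot(inherits(fit, "trend_fit"))
  rng <- fit$x_range
  pad <- guard * diff(rng)
  if (any(x < rng[1] - pad | x > rng[2] + pad))
    warning(sprintf("predictor value outside the fitted range [%g, %g]: extrapolating",
                    rng[1], rng[2]))
  out <- fit$predict(x)
  if (bias_correct && fit$model == "log-linear") {
    sigma2 <- sum(fit$residuals^2) / (fit$n - 2)
    out <- out * exp(sigma2 / 2)
  }
  out
}
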