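# Wheat-productivity volatility estimation.
#
# Yearly productivity series (production per harvested area) are standardized
# to the reference year, an ARIMA model is fitted to the standardized series
# with AIC order selection over (p, q) in [0, max_p] x [0, max_q] at fixed
# differencing order d (default 1: the model is written on first differences),
# and the residual standard deviation sigma_r feeds the Monte Carlo shock
# generator.  Boundary moving-average fits (|theta| >= 0.999), which arise
# routinely when near-trend-stationary series are first-differenced, are
# accepted but flagged.

#' Generate a synthetic yearly yield series with known data-generating process
#'
#' With `d = 0` (default) the standardized productivity level is stationary
#' around 1: `x_t = 1 + ARMA(ar, ma)` with innovation standard deviation `sd`.
#' With `d = 1` the first differences follow the ARMA process and the level is
#' anchored at 1 in the reference year.  The innovations are attached as an
#' attribute so generator-level convergence checks need no model fitting.
#'
#' @param region region label.
#' @param ar,ma ARMA coefficient vectors (may be empty); the AR polynomial
#'   must be stationary and the MA polynomial invertible.
#' @param sd innovation standard deviation (>= 0; 0 gives a constant series).
#' @param n_years series length (>= 20 for downstream fitting).
#' @param seed integer seed.
#' @param d 0 for a stationary level around 1, 1 for ARMA first differences.
#' @param end_year calendar year of the last observation, which is flagged as
#'   the reference year.
#' @return a `yield_series` data frame with columns `year`, `value`.
#' @export
generate_yield_series <- function(region, ar = numeric(0), ma = numeric(0),
                                  sd = 0.1, n_years = 25, seed = 1L,
                                  d = 0, end_year = 2016L) {
  if (sd < 0) stopf("generate_yield_series: innovation sd must be >= 0")
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1))
    stopf("generate_yield_series: non-stationary AR polynomial")
  if (length(ma) && any(Mod(polyroot(c(1, ma))) < 1))
    stopf("generate_yield_series: non-invertible MA polynomial")
  with_seed(seed, {
    innov <- stats::rnorm(n_years, 0, sd)
    z <- if (sd == 0) rep(0, n_years)
    else as.numeric(stats::arima.sim(
      model = list(ar = ar, ma = ma), n = n_years, innov = innov,
      n.start = 60, start.innov = stats::rnorm(60, 0, sd)))
    if (d == 0) {
      x <- 1 + z
    } else if (d == 1) {
      s <- cumsum(z)
      x <- 1 + s - s[n_years]          # anchored at 1 in the reference year
    } else stopf("generate_yield_series: d must be 0 or 1")
    if (any(x <= 0))
      stopf("generate_yield_series: simulated productivity went non-positive (sd too large for n_years); region '%s'", region)
    years <- seq.int(end_year - n_years + 1L, end_year)
    structure(data.frame(year = years, value = x),
              class = c("yield_series", "data.frame"),
              region = region, reference_year = end_year,
              innovations = innov, dgp = list(ar = ar, ma = ma, sd = sd, d = d))
  })
}

#' Coerce a data frame to a yield series
#'
#' @param df data frame with `year` and `value` (or `production` and
#'   `area_harvested`, from which productivity is computed).
#' @param region region label.
#' @param reference_year the standardization year; must be present.
#' @export
as_yield_series <- function(df, region, reference_year) {
  if (!"value" %in% names(df)) {
    if (all(c("production", "area_harvested") %in% names(df)))
      df$value <- df$production / df$area_harvested
    else stopf("as_yield_series: need 'value' or 'production'+'area_harvested'")
  }
  if (!reference_year %in% df$year)
    stopf("as_yield_series: reference year %s not present", reference_year)
  if (any(df$value <= 0))
    stopf("as_yield_series: productivity values must be strictly positive")
  structure(df[order(df$year), c("year", "value")],
            class = c("yield_series", "data.frame"),
            region = region, reference_year = reference_year)
}

#' Standardize a yield series to its reference year
#'
#' Divides every value by the reference-year value, so the reference-year
#' entry becomes exactly 1; idempotent.
#'
#' @param series a `yield_series`.
#' @export
standardize <- function(series) {
  stopifnot(inherits(series, "yield_series"))
  ref <- attr(series, "reference_year")
  k <- match(ref, series$year)
  if (is.na(k)) stopf("standardize: reference year %s missing from series", ref)
  v <- series$value[k]
  if (!(v > 0)) stopf("standardize: reference-year value must be > 0")
  out <- series
  out$value <- series$value / v
  out
}

#' Fit an ARIMA model with AIC order selection
#'
#' Standardizes the series, then fits `arima(x, order = c(p, d, q))` by exact
#' maximum likelihood for every `(p, q)` in the grid and keeps the fit with
#' the smallest AIC; ties break toward smaller `p + q`, then smaller `p`.
#' Conditional-sum-of-squares is used as a fallback when exact ML fails (its
#' AIC is then approximated as `n log(sigma^2) + 2k`).  A series whose
#' d-times-differenced values are constant yields the null fit
#' `(p, q) = (0, 0)` with `sigma_r = 0`.
#'
#' @param series a `yield_series`.
#' @param max_p,max_q maximal AR and MA orders (default 3).
#' @param d differencing order (default 1).
#' @return an `arima_fit` with elements `p`, `q`, `d`, `ar`, `ma`,
#'   `residuals`, `sigma`, `aic`, `boundary_ma`, `method`.
#' @export
fit_arima <- function(series, max_p = 3, max_q = 3, d = 1) {
  stopifnot(inherits(series, "yield_series"))
  x <- standardize(series)$value
  n <- length(x)
  if (n <= max_p + max_q + d + 1)
    stopf("fit_arima: series length %d too short for max orders (%d,%d) with d=%d",
          n, max_p, max_q, d)
  region <- attr(series, "region") %||% NA_character_

  dx <- if (d > 0) diff(x, differences = d) else x
  if (stats::sd(dx) < 1e-12) {
    return(structure(list(region = region, p = 0L, q = 0L, d = d,
                          ar = numeric(0), ma = numeric(0),
                          residuals = rep(0, length(dx)), sigma = 0,
                          aic = -Inf, boundary_ma = FALSE, method = "null"),
                     class = "arima_fit"))
  }

  grid <- expand.grid(p = 0:max_p, q = 0:max_q)
  grid <- grid[order(grid$p + grid$q, grid$p), ]
  best <- NULL; attempted <- character(0)
  for (k in seq_len(nrow(grid))) {
    p <- grid$p[k]; q <- grid$q[k]
    attempted <- c(attempted, sprintf("(%d,%d,%d)", p, d, q))
    fit <- tryCatch(
      list(f = stats::arima(x, order = c(p, d, q), method = "ML",
                            include.mean = d == 0), method = "ML"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        list(f = stats::arima(x, order = c(p, d, q), method = "CSS",
                              include.mean = d == 0), method = "CSS"),
        error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    f <- fit$f
    aic <- f$aic
    if (is.null(aic) || is.na(aic))
      aic <- length(dx) * log(max(f$sigma2, 1e-300)) + 2 * (p + q + 1)
    # strict improvement keeps the first (smallest p+q, then p) of any tie
    if (is.null(best) || aic < best$aic - 1e-9)
      best <- list(p = p, q = q, aic = aic, f = f, method = fit$method)
  }
  if (is.null(best))
    stopf("fit_arima: no candidate order converged; attempted %s",
          paste(attempted, collapse = " "))
  f <- best$f
  cf <- stats::coef(f)
  ar <- unname(cf[grep("^ar", names(cf))])
  ma <- unname(cf[grep("^ma", names(cf))])
  resid <- as.numeric(stats::residuals(f))
  structure(list(region = region, p = as.integer(best$p),
                 q = as.integer(best$q), d = d, ar = ar, ma = ma,
                 residuals = resid, sigma = stats::sd(resid),
                 aic = best$aic,
                 boundary_ma = length(ma) > 0 && any(abs(ma) >= 0.999),
                 method = best$method),
            class = "arima_fit")
}

#' @export
print.arima_fit <- function(x, ...) {
  cat(sprintf("<arima_fit> region %s: ARIMA(%d,%d,%d), sigma_r = %.4f, AIC = %.2f%s\n",
              x$region, x$p, x$d, x$q, x$sigma, x$aic,
              if (x$boundary_ma) " [boundary MA]" else ""))
  invisible(x)
}

#' Residual standard deviation of a fitted ARIMA model
#'
#' Sample convention (n - 1 denominator) over the stored residual vector.
#'
#' @param fit an `arima_fit`.
#' @export
residual_sd <- function(fit) {
  stopifnot(inherits(fit, "arima_fit"))
  if (length(fit$residuals) < 2) return(0)
  stats::sd(fit$residuals)
}

#' Volatility summary table across regions
#'
#' One row per fitted region with AR/MA coefficients padded to three terms and
#' the residual standard deviation -- the shape of the published volatility
#' table.  Boundary MA fits are flagged.
#'
#' @param fits list of `arima_fit` objects.
#' @export
volatility_table <- function(fits) {
  pad <- function(v) c(v, rep(NA_real_, 3))[1:3]
  do.call(rbind, lapply(fits, function(f) {
    data.frame(region = f$region,
               delta1 = pad(f$ar)[1], delta2 = pad(f$ar)[2],
               delta3 = pad(f$ar)[3],
               theta1 = pad(f$ma)[1], theta2 = pad(f$ma)[2],
               theta3 = pad(f$ma)[3],
               sd = f$sigma, boundary_ma = f$boundary_ma)
  }))
}

#' Null volatility fit for a non-producing region
#'
#' Regions that do not grow wheat carry `sigma_r = 0`, so their Monte Carlo
#' shock multiplier is always 1.
#'
#' @param region region label.
#' @export
null_fit <- function(region) {
  structure(list(region = region, p = 0L, q = 0L, d = 1L,
                 ar = numeric(0), ma = numeric(0), residuals = numeric(0),
                 sigma = 0, aic = NA_real_, boundary_ma = FALSE,
                 method = "null"),
            class = "arima_fit")
}
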