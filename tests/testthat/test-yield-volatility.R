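# Volatility estimation: standardization, AIC-selected ARIMA fits, residual
# standard deviations, and parameter-recovery oracles against the generator.

mk_series <- function(values, years = seq_along(values) + 1991,
                      ref = max(years)) {
  as_yield_series(data.frame(year = years, value = values), "T", ref)
}

test_that("standardize is the forced division by the reference-year value", {
  s <- mk_series(c(2, 4))
  out <- standardize(s)
  expect_equal(out$value, c(0.5, 1))
  # identity when already 1 at the reference year
  s1 <- mk_series(c(0.9, 1))
  expect_equal(standardize(s1)$value, s1$value)
  # idempotence
  expect_equal(standardize(standardize(s))$value, standardize(s)$value)
})

test_that("standardize rejects a missing reference year", {
  s <- mk_series(c(2, 4))
  attr(s, "reference_year") <- 1800
  expect_error(standardize(s), "reference year")
})

test_that("white-noise input recovers the innovation SD within 10% (derived oracle)", {
  ys <- generate_yield_series("W", sd = 0.05, n_years = 2000, seed = 9)
  f <- fit_arima(ys, d = 0)
  expect_lt(abs(f$sigma - 0.05) / 0.05, 0.10)
  # the AIC-selected model never beats worse than the (0,0) model
  f00 <- fit_arima(ys, max_p = 0, max_q = 0, d = 0)
  expect_lte(f$aic, f00$aic + 1e-9)
})

test_that("a constant series yields the null fit with sigma 0", {
  f <- fit_arima(generate_yield_series("C", sd = 0, n_years = 30, seed = 1))
  expect_identical(c(f$p, f$q), c(0L, 0L))
  expect_identical(f$sigma, 0)
})

test_that("ARIMA(1,1,1) with well-identified coefficients is recovered within 0.1 at n = 5000", {
  ys <- generate_yield_series("Y", ar = 0.5, ma = -0.6, sd = 0.005,
                              n_years = 5000, seed = 4, d = 1)
  f <- fit_arima(ys, d = 1)
  expect_identical(c(f$p, f$q), c(1L, 1L))
  expect_lt(abs(f$ar[1] - 0.5), 0.1)
  expect_lt(abs(f$ma[1] - (-0.6)), 0.1)
  expect_lt(abs(f$sigma - 0.005) / 0.005, 0.10)
})

test_that("residual_sd uses the sample convention and matches a two-pass oracle", {
  f <- null_fit("Z")
  f$residuals <- rep(0, 10)
  expect_identical(residual_sd(f), 0)
  f$residuals <- c(-0.3, 0.3)
  expect_equal(residual_sd(f), 0.3 * sqrt(2))   # n-1 denominator
  set.seed(5)
  r <- rnorm(37)
  f$residuals <- r
  two_pass <- sqrt(sum((r - sum(r) / length(r))^2) / (length(r) - 1))
  expect_equal(residual_sd(f), two_pass, tolerance = 1e-14)
})

test_that("sigma_r is invariant to region label and to common scaling of the series", {
  set.seed(21)
  v <- exp(cumsum(rnorm(25, 0, 0.05))) + 0.5
  s1 <- as_yield_series(data.frame(year = 1992:2016, value = v), "A", 2014)
  s2 <- as_yield_series(data.frame(year = 1992:2016, value = 7.3 * v), "B", 2014)
  f1 <- fit_arima(s1); f2 <- fit_arima(s2)
  # identical up to optimizer noise: standardization maps both to the same
  # series modulo floating-point rounding of the division
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-4)
})

test_that("the full pipeline recovers generating SDs at n = 25 (median within 25%)", {
  set.seed(31)
  for (sig in c(0.07, 0.2)) {
    ratios <- replicate(20, {
      s <- generate_yield_series("M", ar = -0.3, sd = sig, n_years = 25,
                                 seed = sample.int(1e6, 1))
      fit_arima(s)$sigma / sig
    })
    expect_gt(median(ratios), 0.75)
    expect_lt(median(ratios), 1.25)
  }
})

test_that("volatility_table has the published table shape and flags boundary MA", {
  fits <- list(null_fit("NOWHEAT"),
               fit_arima(generate_yield_series("A", ar = 0.4, sd = 0.1,
                                               n_years = 25, seed = 12)))
  vt <- volatility_table(fits)
  expect_identical(names(vt), c("region", "delta1", "delta2", "delta3",
                                "theta1", "theta2", "theta3", "sd",
                                "boundary_ma"))
  expect_identical(vt$sd[1], 0)
  expect_type(vt$boundary_ma, "logical")
})

test_that("fit_arima rejects series too short for the order grid", {
  expect_error(fit_arima(generate_yield_series("S", sd = 0.05, n_years = 8,
                                               seed = 1)),
               "too short")
})
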