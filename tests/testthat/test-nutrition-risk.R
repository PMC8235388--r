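# Nutrition accounting: linear supply/requirement arithmetic, the worst-tail
# order statistic against a brute-force sort oracle and the analytic uniform
# quantile, NAR identities, and return-period amplification.

test_that("nutrient_supply is the unit-checked elementwise product", {
  prof <- setNames(c(0.1, 3.34, 0.035, 0.026, 0.0004, 1.26), NUTRIENTS)
  expect_equal(unname(nutrient_supply(0, prof)), rep(0, 6))
  expect_equal(unname(nutrient_supply(100, prof)[["protein"]]), 10)
  expect_equal(nutrient_supply(2 * 57, prof), 2 * nutrient_supply(57, prof))
  expect_error(nutrient_supply(10, prof[-1]), "lacks nutrient")
})

test_that("population_requirement matches a spreadsheet-style recomputation", {
  # single stratum, one person, 50/day, no births: 18,250 per year
  pyr1 <- data.frame(stratum = "a", count = 1)
  rni1 <- data.frame(stratum = "a", protein = 50)
  expect_equal(unname(population_requirement(pyr1, rni1)[["protein"]]), 18250)
  # four-stratum toy pyramid, recomputed by hand
  pyr <- data.frame(stratum = c("c", "w", "m", "e"),
                    count = c(1000, 1500, 1400, 600))
  rni <- data.frame(stratum = c("c", "w", "m", "e"),
                    protein = c(30, 46, 56, 50),
                    energy = c(1800, 2100, 2500, 1900),
                    iron = c(16, 20, 14, 12),
                    zinc = c(6, 7, 10, 8),
                    folate = c(300, 400, 400, 350),
                    magnesium = c(180, 220, 260, 224))
  preg <- c(protein = 10, energy = 300, iron = 10, zinc = 3, folate = 200,
            magnesium = 40)
  got <- population_requirement(pyr, rni, births = 120,
                                biomass_adjustment = 1.05,
                                pregnancy_increment = preg)
  hand <- vapply(NUTRIENTS, function(n)
    sum(pyr$count * rni[[n]]) * 365 + 120 * preg[[n]] * 365, numeric(1))
  hand[c("protein", "energy")] <- hand[c("protein", "energy")] * 1.05
  expect_equal(got[NUTRIENTS], hand[NUTRIENTS], tolerance = 1e-12)
  # zero births: increment contributes nothing
  g0 <- population_requirement(pyr, rni, births = 0,
                               pregnancy_increment = preg)
  h0 <- vapply(NUTRIENTS, function(n) sum(pyr$count * rni[[n]]) * 365,
               numeric(1))
  expect_equal(g0[NUTRIENTS], h0[NUTRIENTS])
  expect_error(population_requirement(
    data.frame(stratum = "x", count = 5), rni, 0), "no intake")
})

test_that("value_at_risk is the ceiling(p n)-th order statistic (sort oracle)", {
  d <- c(-10, -5, rep(0, 18))
  expect_identical(value_at_risk(d, 0.05), -10)
  expect_identical(value_at_risk(rep(0, 100), 0.05), 0)
  set.seed(77)
  for (k in 1:50) {
    n <- sample(10:2000, 1)
    p <- runif(1, 0.005, 0.49)
    x <- rnorm(n) * 10
    expect_identical(value_at_risk(x, p), sort(x)[ceiling(p * n)])
  }
  expect_error(value_at_risk(numeric(0), 0.05), "empty")
  expect_error(value_at_risk(d, 0.6), "p must")
})

test_that("value_at_risk is non-decreasing in p", {
  set.seed(13)
  x <- rnorm(500)
  ps <- sort(runif(20, 0.01, 0.49))
  vs <- vapply(ps, function(p) value_at_risk(x, p), numeric(1))
  expect_true(all(diff(vs) >= 0))
})

test_that("the 5% VaR of 1000 uniform(-1, 0) draws is -0.95 (analytic oracle)", {
  set.seed(2024)
  vars <- replicate(100, value_at_risk(runif(1000, -1, 0), 0.05))
  expect_lt(abs(mean(vars) - (-0.95)), 0.02)
})

test_that("NAR is the sign-preserving product of VaR and contribution share", {
  expect_equal(nar(-10, c(protein = 1))$nar, -10)
  expect_equal(nar(-10, c(magnesium = 2))$nar, -20)
  expect_equal(nar(-33, c(iron = 0))$nar, 0)
  # linearity in both arguments
  sh <- setNames(runif(6), NUTRIENTS)
  expect_equal(nar(-8, 2 * sh)$nar, 2 * nar(-8, sh)$nar)
  expect_equal(nar(-16, sh)$nar, 2 * nar(-8, sh)$nar)
})

test_that("the worst-tail consistency pattern reproduces as an arithmetic identity", {
  # a region with a 13.7% worst-tail consumption loss and back-solved shares
  shares <- c(protein = 18.0 / 13.7, magnesium = 37.4 / 13.7)
  out <- nar(-13.7, shares)
  expect_equal(out$nar, c(-18.0, -37.4), tolerance = 1e-12)
})

test_that("return-period amplification: identity, bound, and pairing checks", {
  set.seed(9)
  y <- rnorm(500)
  expect_equal(return_period_amplification(y, y, 0.05)$probability, 0.05)
  shifted <- y - (max(y) - min(y)) - 1
  expect_equal(return_period_amplification(y, shifted, 0.05)$probability, 1)
  a <- structure(y, seed = 1L); b <- structure(y, seed = 2L)
  expect_error(return_period_amplification(a, b), "not paired")
  expect_error(return_period_amplification(y, y[-1]), "not paired")
})

test_that("nar_table flags losses beyond the 5%-of-requirement threshold", {
  dist <- structure(matrix(c(rep(-20, 5), rep(0, 15),
                             rep(-1, 5), rep(0, 15)), 20, 2,
                           dimnames = list(NULL, c("A", "B"))),
                    scenario = "Y")
  shares <- matrix(1, 2, 6, dimnames = list(c("A", "B"), NUTRIENTS))
  nt <- nar_table(dist, shares, p = 0.05)
  expect_true(nt$flagged[nt$region == "A"])
  expect_false(nt$flagged[nt$region == "B"])
  expect_equal(nt$protein, nt$var_consumption_change)
})
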