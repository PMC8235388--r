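# Equilibrium core: calibration identity, bookkeeping census, shock locality,
# solver trivials, continuity against a finite-difference oracle, Walras'
# law, homogeneity, quota complementarity, and the directional trade
# mechanism.

test_that("the all-ones system has zero residual and solves to the benchmark", {
  pp <- toy_params()
  sys <- build_system(pp)
  expect_lt(max(abs(sys$residual(numeric(sys$n_unknowns)))), 1e-8 * max(pp$Z0))
  sol <- solve_equilibrium(sys)
  expect_s3_class(sol, "cge_solution")
  expect_equal(sol$C, pp$C0, tolerance = 1e-10)
  expect_equal(unname(sol$wL), rep(1, 3), tolerance = 1e-10)
  expect_equal(sol$Z, pp$Z0, tolerance = 1e-10)
})

test_that("equation and unknown censuses are printed and equal", {
  sys <- build_system(toy_params())
  expect_equal(sum(sys$census_equations), sum(sys$census_unknowns),
               ignore_attr = TRUE)
  out <- capture.output(print(sys))
  totals <- grep("TOTAL", out, value = TRUE)
  expect_length(totals, 2)
  expect_identical(totals[1], totals[2])
})

test_that("a wheat shifter perturbs only that region's wheat blocks at the benchmark point", {
  pp <- toy_params()
  sh <- unit_shock(pp); sh["REG2"] <- 0.9
  sys <- build_system(pp, sh)
  r <- sys$residual(numeric(sys$n_unknowns))
  S <- length(pp$sectors); R <- length(pp$regions)
  zp <- matrix(r[1:(S * R)], S, R, dimnames = dimnames(pp$Z0))
  expect_gt(abs(zp[pp$wheat_sector, "REG2"]), 1e-3)
  expect_lt(max(abs(zp[setdiff(pp$sectors, pp$wheat_sector), ])), 1e-10)
  expect_lt(max(abs(zp[, c("REG1", "REG3")])), 1e-10)
  # labor block untouched at the benchmark point (demand is price-driven)
  lab <- r[(2 * S * R + 1):(2 * S * R + R - 1)]
  expect_lt(max(abs(lab)), 1e-10)
})

test_that("equal shocks on a symmetric world give a symmetric solution", {
  pp <- sym_params()
  sh <- stats::setNames(c(0.8, 0.8), c("A", "B"))
  sol <- solve_equilibrium(pp, shock = sh)
  expect_s3_class(sol, "cge_solution")
  expect_equal(unname(sol$wL["A"]), unname(sol$wL["B"]), tolerance = 1e-8)
  expect_equal(unname(sol$C[, "A"]), unname(sol$C[, "B"]), tolerance = 1e-8)
  expect_equal(unname(sol$pq[, "A"]), unname(sol$pq[, "B"]), tolerance = 1e-8)
})

test_that("tiny shocks give first-order responses matching a finite difference", {
  pp <- toy_params()
  h <- 1e-3
  up <- unit_shock(pp); up["REG1"] <- 1 + h
  dn <- unit_shock(pp); dn["REG1"] <- 1 - h
  solp <- solve_equilibrium(pp, shock = up)
  soln <- solve_equilibrium(pp, shock = dn)
  dCp <- solp$C - pp$C0
  dCn <- soln$C - pp$C0
  # first-order: responses are antisymmetric up to O(h^2)
  expect_lt(max(abs(dCp + dCn)), 0.05 * max(abs(dCp - dCn)))
  # and the solution stays in a neighborhood of the benchmark
  expect_lt(max(abs(solp$pq - 1)), 0.05)
})

test_that("Walras' law: dropped labor market and every balance of payments clear", {
  pp <- toy_params()
  sh <- stats::setNames(c(0.7, 1.1, 0.85), pp$regions)
  sol <- solve_equilibrium(pp, shock = sh)
  expect_lt(abs(excess_demand(sol, "walras")), 1e-6)
  for (r in pp$regions)
    expect_lt(abs(excess_demand(sol, paste0("bop:", r))), 1e-6)
  expect_lt(abs(excess_demand(sol, "numeraire")), 1e-9)
  # solved markets clear to solver tolerance
  expect_lt(abs(excess_demand(sol, paste0("good:wheat:", pp$regions[2]))), 1e-7)
  expect_error(excess_demand(sol, "good:unobtainium:REG1"), "unknown market")
})

test_that("excess demand is nonzero away from equilibrium", {
  pp <- toy_params()
  sys <- build_system(pp, stats::setNames(c(0.9, 1, 1), pp$regions))
  r <- sys$residual(numeric(sys$n_unknowns))   # benchmark prices, shocked world
  expect_gt(max(abs(r)), 1e-3)
})

test_that("re-normalizing the numeraire leaves real quantities unchanged", {
  pp <- toy_params()
  sh <- stats::setNames(c(0.8, 1, 1.05), pp$regions)
  s1 <- solve_equilibrium(build_system(pp, sh, numeraire = 1))
  s2 <- solve_equilibrium(build_system(pp, sh, numeraire = 2))
  expect_equal(s2$Pnum, 2, tolerance = 1e-10)
  expect_equal(s2$C, s1$C, tolerance = 1e-8)
  expect_equal(s2$Z, s1$Z, tolerance = 1e-8)
  expect_equal(s2$Eb, s1$Eb, tolerance = 1e-8)
  # nominal prices scale with the numeraire
  expect_equal(s2$pq / s1$pq, matrix(2, nrow(s1$pq), ncol(s1$pq)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("solving is deterministic given identical inputs", {
  pp <- toy_params()
  sh <- stats::setNames(c(0.75, 1, 1), pp$regions)
  s1 <- solve_equilibrium(pp, shock = sh)
  s2 <- solve_equilibrium(pp, shock = sh)
  expect_identical(s1$u, s2$u)
})

test_that("quota complementarity holds and fraction-1 quotas reproduce the benchmark", {
  pp <- toy_params()
  # binding case: exporter hit by a bad harvest would otherwise export less,
  # so use a good harvest abroad to push REG1 exports over a tight ceiling
  q <- quota_baseline(pp, "REG1", 0.5)
  sh <- stats::setNames(c(0.85, 1, 1), pp$regions)
  sol <- solve_equilibrium(pp, shock = sh, quotas = q)
  expect_s3_class(sol, "cge_solution")
  w <- pp$wheat_sector
  for (k in seq_len(nrow(q))) {
    ex <- sol$Eb[w, q$from[k], q$to[k]]
    clamped <- !is.null(sol$quota_info) &&
      any(sol$quota_info$to == q$to[k], na.rm = TRUE)
    if (clamped) {
      ri <- which(sol$quota_info$to == q$to[k])
      expect_equal(ex, q$ceiling[k], tolerance = 1e-7)
      expect_gte(sol$quota_info$rent_per_unit[ri], -1e-7)
    } else {
      expect_lte(ex, q$ceiling[k] * (1 + 1e-7))
    }
  }
  # quota rents reach the exporting household: income above factor payments
  expect_gt(sol$rent["REG1"], 0)
  # non-binding limit: fraction-1 ceilings with unit shocks are Reference
  q1 <- quota_baseline(pp, "REG1", 1)
  solb <- solve_equilibrium(pp, shock = unit_shock(pp), quotas = q1)
  expect_equal(solb$C, pp$C0, tolerance = 1e-10)
  expect_true(is.null(solb$quota_info) || nrow(solb$quota_info) == 0)
})

test_that("aggregate-quota variant clamps total exports with nonnegative rent", {
  pp <- toy_params()
  qa <- quota_baseline(pp, "REG1", 0.6, aggregate = TRUE)
  sol <- solve_equilibrium(pp, shock = unit_shock(pp), quotas = qa)
  expect_s3_class(sol, "cge_solution")
  w <- pp$wheat_sector
  expect_equal(sol$Eagg[w, "REG1"], qa$ceiling[1], tolerance = 1e-7)
  expect_gte(sol$quota_info$rent_per_unit[1], -1e-9)
  expect_lt(abs(excess_demand(sol, "walras")), 1e-6)
})

test_that("a dominant exporter's wheat crash hurts the importer monotonically", {
  pp <- toy_params()
  imp <- importer_of(pp)
  w <- pp$wheat_sector
  cons <- numeric(0); price <- numeric(0)
  for (a in c(1, 0.85, 0.7)) {
    sh <- unit_shock(pp); sh["REG1"] <- a
    sol <- solve_equilibrium(pp, shock = sh)
    cons <- c(cons, sol$C[w, imp])
    price <- c(price, sol$pq[w, imp])
  }
  expect_true(all(diff(cons) < 0))   # strictly decreasing consumption
  expect_true(all(diff(price) > 0))  # strictly increasing composite price
})

test_that("build_system enforces the shock floor and quota name checks", {
  pp <- toy_params()
  sh <- unit_shock(pp); sh["REG1"] <- 0.2
  expect_error(build_system(pp, sh), "0.3 floor")
  qbad <- data.frame(sector = "gold", from = "REG1", to = "REG2", ceiling = 1)
  expect_error(build_system(pp, quotas = qbad), "unknown sector")
})
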