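# Synthetic world generators: balanced SAMs, yield series with known
# data-generating process, and internally consistent nutrition tables.

test_that("generated SAMs are balanced for 100 random specs", {
  set.seed(303)
  for (k in 1:100) {
    nr <- sample(2:4, 1)
    sp <- world_spec(regions = paste0("R", seq_len(nr)),
                     export_share = runif(1, 0, 0.3),
                     savings_rate = runif(1, 0.2, 0.35),
                     seed = sample.int(1e6, 1))
    sam <- generate_sam(sp)
    gap <- max(abs(rowSums(sam) - colSums(sam))) / max(sam)
    expect_lt(gap, 1e-8)
    expect_true(all(sam >= 0))
  }
})

test_that("a mirrored two-region spec yields a SAM invariant under relabelling", {
  sp <- world_spec(regions = c("A", "B"), symmetric = TRUE,
                   export_share = 0.2, seed = 7)
  sam <- generate_sam(sp)
  swapped <- chartr("AB", "BA", rownames(sam))
  m <- sam[match(rownames(sam), swapped), match(colnames(sam), swapped)]
  expect_equal(max(abs(m - sam)), 0)
})

test_that("zero trade intensity gives an autarkic SAM with empty trade accounts", {
  sam <- generate_sam(world_spec(export_share = 0, seed = 3))
  trd <- grep("^trd:", rownames(sam))
  expect_true(length(trd) > 0)
  expect_identical(sum(sam[trd, ]) + sum(sam[, trd]), 0)
})

test_that("SAM generation is deterministic in the seed and rejects infeasible specs", {
  expect_identical(generate_sam(world_spec(seed = 5)),
                   generate_sam(world_spec(seed = 5)))
  expect_false(identical(generate_sam(world_spec(seed = 5)),
                         generate_sam(world_spec(seed = 6))))
  # a dominant exporter with near-zero savings cannot fund its trade surplus
  expect_error(generate_sam(world_spec(savings_rate = 0.01, seed = 5)),
               "region", fixed = FALSE)
})

test_that("world_spec validates its invariants", {
  expect_error(world_spec(food_sectors = c("ofood")), "wheat")
  expect_error(world_spec(export_share = 1.2), "export shares")
  expect_error(world_spec(sigma_va = -1), "elasticities")
  expect_error(world_spec(regions = "solo"), "2 regions")
})

test_that("SAM csv round trip preserves the matrix", {
  sam <- generate_sam(world_spec(seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sam_csv(sam, f)
  back <- read_sam_csv(f, account_order = rownames(sam))
  expect_equal(max(abs(back - sam)), 0, tolerance = 1e-12)
})

test_that("yield generator: zero sd gives a constant series; same seed reproduces", {
  ys <- generate_yield_series("R", sd = 0, n_years = 25, seed = 1)
  expect_true(all(ys$value == 1))
  expect_identical(generate_yield_series("R", sd = 0.1, seed = 2),
                   generate_yield_series("R", sd = 0.1, seed = 2))
  expect_false(identical(generate_yield_series("R", sd = 0.1, seed = 2)$value,
                         generate_yield_series("R", sd = 0.1, seed = 3)$value))
})

test_that("yield generator rejects a non-stationary AR polynomial", {
  expect_error(generate_yield_series("R", ar = 1.01, sd = 0.1, seed = 1),
               "non-stationary")
})

test_that("empirical innovation SD converges to the specified SD at rate 3/sqrt(n)", {
  for (n in c(100, 1000, 5000)) {
    ys <- generate_yield_series("R", ar = 0.3, sd = 0.2, n_years = n,
                                seed = 99)
    emp <- sd(attr(ys, "innovations"))
    expect_lt(abs(emp - 0.2) / 0.2, 3 / sqrt(n))
  }
})

test_that("nutrition tables: target share 1 round-trips exactly through the calculators", {
  regs <- c("R1", "R2")
  tgt <- matrix(1, 2, length(NUTRIENTS),
                dimnames = list(regs, NUTRIENTS))
  tgt["R2", ] <- c(1.31, 0.5, 0.48, 0.8, 0.3, 2.73)
  tabs <- generate_nutrition_tables(regs, target_shares = tgt, seed = 4)
  sh <- contribution_share(tabs)
  expect_equal(unname(sh["R1", ]), rep(1, length(NUTRIENTS)), tolerance = 1e-12)
  expect_equal(unname(sh["R2", ]), unname(tgt["R2", ]), tolerance = 1e-12)
})

test_that("zero population is rejected; doubling strata counts doubles requirements", {
  tabs <- generate_nutrition_tables("R1", seed = 2)
  pyr <- tabs$pyramid[tabs$pyramid$region == "R1", ]
  expect_error(population_requirement(transform(pyr, count = 0), tabs$rni, 0),
               "zero population")
  r1 <- population_requirement(pyr, tabs$rni, births = 0)
  r2 <- population_requirement(transform(pyr, count = 2 * count), tabs$rni,
                               births = 0)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})
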