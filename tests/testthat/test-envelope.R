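# FBA, production envelopes, coupling classification, MP point, yields.
# Expected numbers are the hand-derivable LP optima of the toy network
# (vertex enumeration), cross-checked against HiGHS during development.

test_that("fba reproduces the toy optima", {
  expect_equal(fba(toy, "R3")$objective, 4.5, tolerance = 1e-8)
  r <- fba(toy, "EX_P", "max", fixed = c(R3 = 0))
  expect_equal(r$objective, 10, tolerance = 1e-8)
  # flux vector satisfies steady state
  expect_lt(max(abs(toy$S %*% r$fluxes)), 1e-8)
  # no carbon, no growth (maintenance relaxed so the model stays feasible)
  blocked <- make_coupling_toy(maintenance_lb = 0, substrate_ub = 0)
  expect_equal(fba(blocked, "R3")$objective, 0, tolerance = 1e-12)
  # infeasibility is signalled, not thrown
  expect_equal(fba(toy, "EX_P", fixed = c(R3 = 99))$status, "infeasible")
})

test_that("wild-type envelope is min 0 / max 10 - g", {
  env <- compute_envelope(toy, TOY_BIOMASS, TOY_PRODUCT, n_points = 50)
  expect_equal(env$max_growth, 4.5, tolerance = 1e-8)
  expect_close(env$min_product, rep(0, 50), tol = 1e-8)
  expect_close(env$max_product, 10 - env$growth_grid, tol = 1e-8)
  expect_equal(env$coupling, "none")
  expect_true(all(diff(env$growth_grid) > 0))
  expect_true(all(env$min_product <= env$max_product + 1e-9))
})

test_that("R5 knockout gives the strongly coupled envelope", {
  ko <- knockout(toy, "R5")
  env <- compute_envelope(ko, TOY_BIOMASS, TOY_PRODUCT, n_points = 50)
  expect_close(env$min_product, env$growth_grid + 1, tol = 1e-8)
  expect_close(env$max_product, 10 - env$growth_grid, tol = 1e-8)
  expect_equal(env$mp_point, c(growth = 4.5, min_product = 5.5,
                               max_product = 5.5), tolerance = 1e-8)
  expect_equal(env$min_production_at_zero_growth, 1, tolerance = 1e-8)
  expect_equal(env$coupling, "strong")
})

test_that("coupling classes follow the zero-growth minimum", {
  # relaxing maintenance turns the same knockout into weak coupling
  weak <- knockout(make_coupling_toy(maintenance_lb = 0), "R5")
  env_w <- compute_envelope(weak, TOY_BIOMASS, TOY_PRODUCT, n_points = 20)
  expect_equal(env_w$coupling, "weak")
  expect_equal(env_w$min_production_at_zero_growth, 0, tolerance = 1e-9)
  expect_gt(max(env_w$min_product), 1e-6)
  # wild type couples nothing
  expect_equal(compute_envelope(toy, TOY_BIOMASS, TOY_PRODUCT,
                                n_points = 10)$coupling, "none")
})

test_that("mp_point matches the envelope endpoints (n_points = 2)", {
  env2 <- compute_envelope(toy, TOY_BIOMASS, TOY_PRODUCT, n_points = 2)
  mp <- mp_point(toy, TOY_BIOMASS, TOY_PRODUCT)
  expect_equal(env2$growth_grid[2], mp[["growth"]], tolerance = 1e-9)
  expect_equal(env2$min_product[2], mp[["min_product"]], tolerance = 1e-9)
  expect_equal(env2$max_product[2], mp[["max_product"]], tolerance = 1e-9)
  expect_equal(mp, c(growth = 4.5, min_product = 0, max_product = 5.5),
               tolerance = 1e-8)
  # fully blocked model collapses to the origin
  blocked <- make_coupling_toy(maintenance_lb = 0, substrate_ub = 0)
  expect_equal(unname(mp_point(blocked, TOY_BIOMASS, TOY_PRODUCT)),
               c(0, 0, 0), tolerance = 1e-10)
})

test_that("knockouts only shrink the envelope pointwise", {
  wt <- compute_envelope(toy, TOY_BIOMASS, TOY_PRODUCT, n_points = 25)
  set.seed(3)
  for (ids in list("R5", "R1", c("R5", "R2"))) {
    ko <- knockout(toy, ids)
    gmax_ko <- fba(ko, TOY_BIOMASS)
    if (gmax_ko$status != "optimal") next      # knockout kills the model
    shared <- wt$growth_grid[wt$growth_grid <= gmax_ko$objective + 1e-9]
    if (length(shared) == 0) next
    for (g in shared[c(1, length(shared))]) {
      wt_i <- which.min(abs(wt$growth_grid - g))
      r_wt <- c(wt$min_product[wt_i], wt$max_product[wt_i])
      # recompute the knockout range exactly at the shared growth value
      mnr <- fba(ko, TOY_PRODUCT, "min", fixed = stats::setNames(g, TOY_BIOMASS))
      mxr <- fba(ko, TOY_PRODUCT, "max", fixed = stats::setNames(g, TOY_BIOMASS))
      if (mnr$status != "optimal") next
      expect_gte(mnr$objective, r_wt[1] - 1e-7)
      expect_lte(mxr$objective, r_wt[2] + 1e-7)
    }
  }
})

test_that("yield conversion reproduces the published g/g figures", {
  # acetate from glucose: 27.49 mmol/gDCW/h at 10 mmol/gDCW/h uptake
  y <- to_yield_units(27.49, 0.06005, 10, 0.18016)
  expect_equal(round(y, 2), 0.92)           # 0.9162..., printed as ~0.91-0.92
  expect_equal(y, 27.49 * 0.06005 / 1.8016, tolerance = 1e-12)
  # growth yield: 0.91 1/h with biomass "weight" 1 g/mmol
  expect_equal(round(to_yield_units(0.91, 1, 10, 0.18016), 2), 0.51)
  expect_equal(to_yield_units(0, 0.06005, 10, 0.18016), 0)
  expect_error(to_yield_units(1, 1, 0, 1), "> 0")
})

test_that("envelope export writes a readable TSV", {
  env <- compute_envelope(toy, TOY_BIOMASS, TOY_PRODUCT, n_points = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- envelope_table(env, f)
  back <- utils::read.delim(f)
  expect_equal(back, df, tolerance = 1e-12)
})
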