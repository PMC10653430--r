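# Knockout-budget MILP (duality reformulation) against exhaustive search.

toy_mar <- find_mar(toy, c(0.135, 9.865), TOY_BIOMASS, TOY_PRODUCT)
toy_protected <- source_ids(toy, toy_mar$active_set)
br_mar <- find_mar(branched, c(0.135, 9.865), TOY_BIOMASS, TOY_PRODUCT)
br_protected <- source_ids(branched, br_mar$active_set)

test_that("budgeted MILP equals brute force for K in 0..2 on both toys", {
  cases <- list(list(m = toy, p = toy_protected),
                list(m = branched, p = br_protected))
  for (cs in cases) {
    for (K in 0:2) {
      milp <- suppressWarnings(
        cap_knockouts(cs$m, cs$p, K, TOY_BIOMASS, TOY_PRODUCT))
      bf <- brute_force_cap(cs$m, cs$p, K, TOY_BIOMASS, TOY_PRODUCT)
      expect_equal(milp$certified_min, bf$certified_min, tolerance = 1e-6,
                   info = paste(cs$m$id, "K =", K))
    }
  }
})

test_that("K = 0 returns the wild-type envelope", {
  d <- cap_knockouts(toy, toy_protected, 0, TOY_BIOMASS, TOY_PRODUCT)
  expect_length(d$knockouts, 0)
  expect_equal(d$certified_min, 0, tolerance = 1e-9)
  wt <- compute_envelope(toy, TOY_BIOMASS, TOY_PRODUCT,
                         n_points = length(d$envelope$growth_grid))
  expect_equal(d$envelope$max_product, wt$max_product, tolerance = 1e-8)
})

test_that("guaranteed minimum is non-decreasing in K", {
  cand_n <- 3   # branched toy has candidates R4, R5, R6
  vals <- vapply(0:cand_n, function(K)
    suppressWarnings(cap_knockouts(branched, br_protected, K, TOY_BIOMASS,
                                   TOY_PRODUCT))$certified_min, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  expect_equal(vals[1], 0, tolerance = 1e-9)
  expect_equal(vals[3], 1, tolerance = 1e-6)    # K = 2 removes both bypasses
})

test_that("K at or above the reinsertion count reproduces that envelope", {
  for (cs in list(list(m = toy, mar = toy_mar, p = toy_protected),
                  list(m = branched, mar = br_mar, p = br_protected))) {
    d_re <- minimal_knockouts(cs$m, cs$mar, TOY_BIOMASS, TOY_PRODUCT)
    d_cap <- suppressWarnings(
      cap_knockouts(cs$m, cs$p, d_re$count, TOY_BIOMASS, TOY_PRODUCT))
    expect_equal(d_cap$certified_min, d_re$min_production, tolerance = 1e-6,
                 info = cs$m$id)
    env_re <- compute_envelope(knockout(cs$m, d_re$knockouts), TOY_BIOMASS,
                               TOY_PRODUCT, n_points = 15)
    env_cap <- compute_envelope(knockout(cs$m, d_cap$knockouts), TOY_BIOMASS,
                                TOY_PRODUCT, n_points = 15)
    expect_equal(env_cap$min_product, env_re$min_product, tolerance = 1e-7)
    expect_equal(env_cap$max_product, env_re$max_product, tolerance = 1e-7)
  }
})

test_that("certificate equals the recomputed inner LP", {
  d <- suppressWarnings(
    cap_knockouts(branched, br_protected, 2, TOY_BIOMASS, TOY_PRODUCT))
  inner <- fba(knockout(branched, d$knockouts), TOY_PRODUCT, "min",
               fixed = stats::setNames(0, TOY_BIOMASS))
  expect_equal(d$certified_min, inner$objective, tolerance = 1e-7)
})

test_that("excessive K is clamped with a warning", {
  expect_warning(cap_knockouts(toy, toy_protected, 5, TOY_BIOMASS, TOY_PRODUCT),
                 "clamped")
})

test_that("negative K is rejected", {
  expect_error(cap_knockouts(toy, toy_protected, -1, TOY_BIOMASS, TOY_PRODUCT),
               "K must be")
})
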