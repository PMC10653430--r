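# Sequential reinsertion: minimal knockouts that preserve the zero-growth
# minimum secretion.

run_reinsertion <- function(model, target = NULL) {
  tp <- if (is.null(target)) primary_target(model, TOY_BIOMASS, TOY_PRODUCT)
        else target
  mar <- find_mar(model, tp, TOY_BIOMASS, TOY_PRODUCT)
  list(mar = mar,
       design = minimal_knockouts(model, mar, TOY_BIOMASS, TOY_PRODUCT))
}

test_that("toy reinsertion keeps only the essential knockout", {
  res <- run_reinsertion(toy)
  d <- res$design
  expect_equal(d$knockouts, "R5")
  expect_equal(d$count, 1)
  expect_equal(d$min_production, 1, tolerance = 1e-8)
  expect_equal(d$coupling, "strong")
  expect_lte(d$count, length(res$mar$removed_set))
})

test_that("a product-disconnected removed reaction is reinserted", {
  # in the branched toy R6 (A -> P) is removed by the MAR but its return
  # cannot lower the zero-growth minimum, so only the two bypasses stay out
  res <- run_reinsertion(branched)
  expect_setequal(res$mar$removed_set, c("R4", "R5", "R6"))
  expect_setequal(res$design$knockouts, c("R4", "R5"))
  expect_equal(res$design$count, length(res$mar$removed_set) - 1)
})

test_that("weak coupling is refused with a diagnostic", {
  weak <- make_coupling_toy(maintenance_lb = 0)
  mar <- find_mar(weak, primary_target(weak, TOY_BIOMASS, TOY_PRODUCT),
                  TOY_BIOMASS, TOY_PRODUCT)
  expect_error(minimal_knockouts(weak, mar, TOY_BIOMASS, TOY_PRODUCT),
               "strong")
})

test_that("the zero-growth minimum never drops below baseline", {
  for (mdl in list(toy, branched, rev_toy)) {
    tp <- primary_target(mdl, TOY_BIOMASS, TOY_PRODUCT)
    mar <- find_mar(mdl, tp, TOY_BIOMASS, TOY_PRODUCT)
    red <- reduce_to_mar(mdl, mar)
    baseline <- fba(red, TOY_PRODUCT, "min",
                    fixed = stats::setNames(0, TOY_BIOMASS))$objective
    d <- suppressWarnings(
      minimal_knockouts(mdl, mar, TOY_BIOMASS, TOY_PRODUCT))
    final <- fba(knockout(mdl, d$knockouts), TOY_PRODUCT, "min",
                 fixed = stats::setNames(0, TOY_BIOMASS))$objective
    expect_gte(final, baseline - 1e-6)
    expect_equal(d$min_production, final, tolerance = 1e-8)
  }
})

test_that("the final knockout set is locally minimal", {
  for (mdl in list(toy, branched)) {
    res <- run_reinsertion(mdl)
    d <- res$design
    red <- reduce_to_mar(mdl, res$mar)
    baseline <- fba(red, TOY_PRODUCT, "min",
                    fixed = stats::setNames(0, TOY_BIOMASS))$objective
    final_model <- knockout(mdl, d$knockouts)
    for (s in d$knockouts) {
      trial <- restore_reactions(final_model, mdl, s)
      m <- fba(trial, TOY_PRODUCT, "min",
               fixed = stats::setNames(0, TOY_BIOMASS))$objective
      expect_lt(m, baseline - 1e-6)   # restoring any knockout breaks coupling
    }
  }
})

test_that("random reinsertion order is reproducible under a seed", {
  tp <- primary_target(branched, TOY_BIOMASS, TOY_PRODUCT)
  mar <- find_mar(branched, tp, TOY_BIOMASS, TOY_PRODUCT)
  set.seed(99)
  a <- minimal_knockouts(branched, mar, TOY_BIOMASS, TOY_PRODUCT,
                         order = "random")
  set.seed(99)
  b <- minimal_knockouts(branched, mar, TOY_BIOMASS, TOY_PRODUCT,
                         order = "random")
  expect_identical(a$knockouts, b$knockouts)
})
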