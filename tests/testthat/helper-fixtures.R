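# Shared fixtures.  All models are generated in code; nothing is downloaded.

toy <- make_coupling_toy()
branched <- make_branched_toy()
rev_toy <- to_irreversible(make_reversible_toy())

TOY_BIOMASS <- "R3"
TOY_PRODUCT <- "EX_P"

# five target points inside the wild-type toy envelope used by the
# MAR-vs-oracle comparisons (growth, production)
TOY_TARGETS <- list(
  c(0.135, 9.865),   # primary (3% of max growth, upper edge)
  c(4.5, 5.5),       # wild-type MP point
  c(4.5, 0),         # product-free fast growth
  c(2.0, 8.0),       # upper edge, mid growth
  c(1.0, 4.0)        # interior point
)

# directory where users may drop BiGG models to enable the genome-scale
# checks; absent in offline runs
bigg_path <- function(file) testthat::test_path("bigg_models", file)

expect_close <- function(object, expected, tol = 1e-6) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %.3g (tol %.1g)",
                              max(abs(object - expected)), tol))
}
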