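# Interior target generation and the scan / comparison table.

test_that("interior targets divide the span into equal distances", {
  primary <- target_point(0.135, 9.865)
  tps <- make_interior_targets(primary, 5.5, n_mid = 3)
  expect_length(tps, 3)
  expect_equal(vapply(tps, `[[`, numeric(1), "production_rate"),
               c(6.59125, 7.6825, 8.77375), tolerance = 1e-12)
  expect_true(all(vapply(tps, `[[`, numeric(1), "growth_rate") == 0.135))
  expect_true(all(vapply(tps, `[[`, character(1), "edge") == "interior"))
  # the published case: 15 points between the MP and primary production
  tps15 <- make_interior_targets(target_point(0.0273, 27.49), 21.39, 15)
  expect_length(tps15, 15)
  p <- vapply(tps15, `[[`, numeric(1), "production_rate")
  expect_close(diff(p), rep((27.49 - 21.39) / 16, 14), tol = 1e-12)
  expect_true(all(p > 21.39 & p < 27.49))
})

test_that("degenerate spans yield empty lists", {
  expect_length(suppressWarnings(make_interior_targets(target_point(1, 5),
                                                       5.5, 3)), 0)
  expect_warning(make_interior_targets(target_point(1, 5), 5.5, 3),
                 "degenerate")
  expect_length(make_interior_targets(target_point(1, 9), 5.5, 0), 0)
})

test_that("scan deduplicates to the single toy design", {
  tab <- scan_targets(toy, TOY_BIOMASS, TOY_PRODUCT, n_mid = 4, n_points = 20)
  expect_s3_class(tab, "comparison_table")
  expect_equal(nrow(tab), 1)                    # all targets give {R5}
  expect_equal(tab$knockout_ids, "R5")
  expect_equal(tab$envelope, 1)
  # ratio column: target production over primary max production at zero growth
  expect_equal(tab$target_ratio[1], 9.865 / 10, tolerance = 1e-6)
  designs <- attr(tab, "designs")
  expect_length(designs, 1)
  # retained metrics match a recomputation from the knockouts
  d <- designs[[1]]
  env <- compute_envelope(knockout(toy, d$knockouts), TOY_BIOMASS,
                          TOY_PRODUCT, n_points = 20)
  expect_equal(d$min_production, env$min_production_at_zero_growth,
               tolerance = 1e-8)
  expect_equal(d$mp_growth, env$mp_point[["growth"]], tolerance = 1e-8)
})

test_that("scan is deterministic (dedup idempotence)", {
  t1 <- scan_targets(branched, TOY_BIOMASS, TOY_PRODUCT, n_mid = 3,
                     n_points = 15)
  t2 <- scan_targets(branched, TOY_BIOMASS, TOY_PRODUCT, n_mid = 3,
                     n_points = 15)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # every retained alternative respects the filters
  prim_min <- t1$min_production[1]
  expect_true(all(t1$min_production >= prim_min - 1e-6))
  expect_true(all(t1$knockouts <= 10))
})

test_that("a zero knockout cap empties the toy table", {
  tab <- scan_targets(toy, TOY_BIOMASS, TOY_PRODUCT, n_mid = 2,
                      max_knockouts = 0, n_points = 10)
  expect_equal(nrow(tab), 0)
})

test_that("comparison table round-trips through TSV and JSON", {
  tab <- scan_targets(toy, TOY_BIOMASS, TOY_PRODUCT, n_mid = 2, n_points = 10)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_comparison(tab, tsv = tsv, json = js)
  back <- utils::read.delim(tsv)
  expect_equal(back$knockout_ids, tab$knockout_ids)
  expect_equal(back$min_production, tab$min_production, tolerance = 1e-9)
  jj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jj$knockouts, tab$knockouts)
})
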