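# Interior target-point scan.
#
# The primary target sits on the upper (maximum production) edge.  Between
# its production level and the MP point of the primary envelope there is a
# vertical band of candidate operating points; dividing that band into
# equally spaced levels and re-running the pipeline at each produces a
# family of alternative envelopes with different knockout sets.  Points
# below the MP production level are skipped — envelopes found there are
# almost never better than the primary one.

#' Generate interior target points
#'
#' `n_mid` production levels equally spaced strictly between the MP-point
#' production of the primary envelope and the primary target's production,
#' all at the primary target's growth rate (spacing
#' `(P_primary - P_mp) / (n_mid + 1)`).
#'
#' @param primary a `target_point` (the upper-edge primary target).
#' @param mp_production production rate at the MP point of the primary
#'   envelope (mmol/gDCW/h); a named `mp_point()` vector is accepted (its
#'   `max_product` entry is used).
#' @param n_mid number of interior points (`>= 0`).
#' @return list of `target_point`s (possibly empty).
#' @export
make_interior_targets <- function(primary, mp_production, n_mid) {
  if (length(mp_production) > 1L)
    mp_production <- mp_production[["max_product"]]
  if (n_mid < 1) return(list())
  if (primary$production_rate <= mp_production + 1e-12) {
    warning("degenerate span: primary production does not exceed MP production")
    return(list())
  }
  step <- (primary$production_rate - mp_production) / (n_mid + 1)
  lapply(seq_len(n_mid), function(k)
    target_point(primary$growth_rate, mp_production + k * step,
                 primary$growth_fraction, "interior"))
}

#' Scan interior target points and build the comparison table
#'
#' Runs the full pipeline (MAR search, reduction, reinsertion) for the
#' primary target and each interior target, deduplicates identical knockout
#' sets, and keeps alternatives whose minimum production is at least the
#' primary envelope's and whose knockout count does not exceed
#' `max_knockouts`.  Infeasible or weakly coupled targets are skipped with
#' a logged reason.
#'
#' @param model irreversible `metabolic_model` with roles classified.
#' @param biomass_id,product_id reaction ids.
#' @param primary a `target_point`; computed at `growth_fraction` of maximal
#'   growth on the upper edge when `NULL`.
#' @param n_mid number of interior targets (default 10).
#' @param max_knockouts knockout-count cap for retained alternatives
#'   (default 10; the primary design is always reported).
#' @param growth_fraction used when `primary` is `NULL` (default 0.03).
#' @param dedup drop duplicate knockout sets (default TRUE).
#' @param n_points envelope grid size for reported metrics.
#' @return object of class `comparison_table`: a data frame of envelope
#'   rows (primary first, ratio column = target production / primary
#'   envelope's maximum production at zero growth) with the full
#'   `knockout_design` objects in `attr(, "designs")` and skip reasons in
#'   `attr(, "skipped")`.
#' @export
scan_targets <- function(model, biomass_id, product_id, primary = NULL,
                         n_mid = 10, max_knockouts = 10,
                         growth_fraction = 0.03, dedup = TRUE,
                         n_points = 100) {
  if (is.null(primary))
    primary <- primary_target(model, biomass_id, product_id, growth_fraction)

  run_one <- function(tp) {
    mar <- find_mar(model, tp, biomass_id, product_id)
    # weakly coupled reductions cannot go through reinsertion; report the
    # step-2 design (all non-MAR reactions knocked out) instead
    tryCatch(minimal_knockouts(model, mar, biomass_id, product_id),
             error = function(e) {
               reduced <- reduce_to_mar(model, mar)
               design_from_model(reduced, source_ids(model, mar$removed_set),
                                 biomass_id, product_id, target = tp,
                                 mar_objective = mar$objective)
             })
  }
  primary_design <- run_one(primary)
  p_env <- primary_design$envelope
  # denominator of the reported ratio: primary envelope's max production
  # at zero growth
  p_max0 <- max_production_at_zero(p_env)

  targets <- make_interior_targets(primary,
                                   primary_design$mp_production_max, n_mid)
  designs <- list(primary_design)
  ratios <- primary$production_rate / p_max0
  skipped <- character()
  for (tp in targets) {
    d <- tryCatch(run_one(tp), error = function(e) conditionMessage(e))
    if (is.character(d)) {
      skipped <- c(skipped, sprintf("target (%.4g, %.4g): %s",
                                    tp$growth_rate, tp$production_rate, d))
      next
    }
    designs[[length(designs) + 1L]] <- d
    ratios <- c(ratios, tp$production_rate / p_max0)
  }

  keep <- rep(TRUE, length(designs))
  if (dedup) {
    keys <- vapply(designs, function(d) paste(sort(d$knockouts), collapse = "|"),
                   character(1))
    keep <- !duplicated(keys)
  }
  # filters: the knockout cap applies to every row, the minimum-production
  # comparison only to alternatives (the primary is its own reference)
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    if (i > 1L &&
        isTRUE(d$min_production < primary_design$min_production - 1e-6))
      keep[i] <- FALSE
    if (d$count > max_knockouts) keep[i] <- FALSE
  }
  designs <- designs[keep]; ratios <- ratios[keep]

  rows <- if (length(designs)) {
    do.call(rbind, lapply(seq_along(designs), function(i)
      design_row(designs[[i]], envelope_no = i)))
  } else {
    data.frame(envelope = integer(), knockouts = integer(),
               min_production = numeric(), max_production = numeric(),
               mp_production = numeric(), mp_growth = numeric(),
               coupling = character(), knockout_ids = character(),
               stringsAsFactors = FALSE)
  }
  rows$target_ratio <- ratios
  structure(rows, class = c("comparison_table", "data.frame"),
            designs = designs, skipped = skipped, primary = primary)
}

max_production_at_zero <- function(env) {
  g0 <- which.min(abs(env$growth_grid))
  env$max_product[g0]
}

#' Write a comparison table as TSV and/or JSON
#'
#' @param tab a `comparison_table`.
#' @param tsv,json optional output paths.
#' @return `tab`, invisibly.
#' @export
write_comparison <- function(tab, tsv = NULL, json = NULL) {
  df <- as.data.frame(tab)
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(tab)
}
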