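# Step 3: sequential reinsertion of removed reactions.
#
# The reduced (MAR-only) model guarantees a minimum product secretion at
# zero growth.  Restoring every removed reaction whose return does not
# lower that guarantee shrinks the knockout list to the reactions that
# actually matter.  Only the zero-growth minimum is preserved; the maximal
# growth point may move, which is expected and reported.

#' Minimal knockout set by sequential reinsertion
#'
#' Iterates over the removed reactions in model order (at the source,
#' reversible-reaction level), tentatively restores each one (both
#' directions), recomputes the minimum product secretion at zero growth,
#' and keeps the reinsertion when the baseline is preserved within `tol`.
#' Reactions still removed at the end are the knockouts.  A removed
#' direction whose partner direction is in the MAR cannot be deleted at the
#' enzyme level, so it is restored unconditionally first (with a warning if
#' that alone breaks the baseline).
#'
#' @param full_model the irreversible model before reduction.
#' @param mar a `mar_result` for `full_model`.
#' @param biomass_id,product_id reaction ids.
#' @param baseline_min guaranteed minimum production of the reduced model at
#'   zero growth; computed from the reduced model when `NULL`.
#' @param order `"model"` (default, deterministic) or `"random"` (uses the
#'   current RNG state; set a seed for reproducibility).
#' @param tol preservation tolerance, mmol/gDCW/h.
#' @return object of class `knockout_design`.
#' @export
minimal_knockouts <- function(full_model, mar, biomass_id, product_id,
                              baseline_min = NULL, order = c("model", "random"),
                              tol = 1e-6) {
  order <- match.arg(order)
  reduced <- reduce_to_mar(full_model, mar)
  min_at_zero <- function(m) {
    r <- fba(m, product_id, "min",
             fixed = stats::setNames(0, biomass_id))
    if (r$status != "optimal") Inf else r$objective   # cannot avoid growing
  }
  # an infinite baseline means zero growth is itself infeasible in the
  # reduced model: coupling tighter than strong, preserved as-is
  if (is.null(baseline_min)) baseline_min <- min_at_zero(reduced)
  if (baseline_min <= tol)
    stop("reduced model is not strongly coupled (minimum secretion at zero ",
         "growth is ", signif(baseline_min, 4), "); reinsertion requires ",
         "strong coupling")

  removed_src <- source_ids(full_model, mar$removed_set)
  full_dirs <- split(full_model$rxn_ids,
                     unname(full_model$original_ids[full_model$rxn_ids]))
  whole <- vapply(removed_src, function(s)
    all(full_dirs[[s]] %in% mar$removed_set), logical(1))

  cur <- reduced
  if (any(!whole)) {
    # half-removed pairs: other direction is in the MAR, not deletable
    cur <- restore_reactions(cur, full_model, removed_src[!whole])
    if (min_at_zero(cur) < baseline_min - tol)
      warning("restoring non-deletable partner directions lowered the ",
              "guaranteed minimum; the MAR relies on blocking one direction ",
              "of a reversible reaction")
  }
  cand <- removed_src[whole]
  if (order == "random") cand <- sample(cand)
  knockouts <- character()
  for (s in cand) {
    trial <- restore_reactions(cur, full_model, s)
    if (min_at_zero(trial) >= baseline_min - tol) {
      cur <- trial
    } else {
      knockouts <- c(knockouts, s)
    }
  }
  design_from_model(cur, knockouts, biomass_id, product_id,
                    target = mar$target, mar_objective = mar$objective,
                    baseline_min = baseline_min)
}

# assemble the reporting object for a final knocked-out model
design_from_model <- function(model, knockouts, biomass_id, product_id,
                              target = NULL, mar_objective = NA_real_,
                              baseline_min = NA_real_, n_points = 100) {
  env <- compute_envelope(model, biomass_id, product_id, n_points = n_points)
  structure(list(
    knockouts = sort(knockouts),
    count = length(knockouts),
    min_production = env$min_production_at_zero_growth,
    max_production = max(env$max_product, na.rm = TRUE),
    mp_growth = env$mp_point[["growth"]],
    mp_production_min = env$mp_point[["min_product"]],
    mp_production_max = env$mp_point[["max_product"]],
    coupling = env$coupling,
    target = target,
    mar_objective = mar_objective,
    baseline_min = baseline_min,
    envelope = env
  ), class = "knockout_design")
}

#' @export
print.knockout_design <- function(x, ...) {
  cat("<knockout_design> ", x$count, " knockouts: ",
      paste(x$knockouts, collapse = ", "), "\n", sep = "")
  cat(sprintf("  production min %.6g / max %.6g; MP point growth %.6g, product [%.6g, %.6g]\n",
              x$min_production, x$max_production, x$mp_growth,
              x$mp_production_min, x$mp_production_max))
  cat("  coupling:", x$coupling, "\n")
  invisible(x)
}

#' One table row of envelope characteristics for a design
#'
#' Columns follow the comparison-table convention: knockout count, minimum
#' and maximum production rate, production and growth rate at the MP point,
#' knockout reaction names.
#'
#' @param design a `knockout_design`.
#' @param envelope_no envelope index for reporting.
#' @return one-row data frame.
#' @export
design_row <- function(design, envelope_no = NA_integer_) {
  data.frame(
    envelope = envelope_no,
    knockouts = design$count,
    min_production = design$min_production,
    max_production = design$max_production,
    mp_production = design$mp_production_max,
    mp_growth = design$mp_growth,
    coupling = design$coupling,
    knockout_ids = paste(design$knockouts, collapse = ","),
    stringsAsFactors = FALSE
  )
}
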