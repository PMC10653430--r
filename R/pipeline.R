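# End-to-end pipeline and the host-comparison workflow.
#
# The three steps: (1) pick a target point on the upper edge of the
# wild-type envelope at a small growth fraction, (2) find the minimal
# active reactions there and drop everything else, (3) reinsert whatever
# can return without lowering the guaranteed minimum secretion.  The scan
# then repeats 2-3 for interior targets, and an optional budget run bounds
# the knockout count.

#' Run the full strain-design pipeline
#'
#' @param model a `metabolic_model`, or a path to an SBML/JSON model file.
#' @param biomass_id,product_id reaction ids (biomass defaults to the
#'   reaction carrying the model objective).
#' @param medium optional `medium_spec` (or path to a medium JSON) applied
#'   before conversion to irreversible form.
#' @param maintenance_ids,diffusion_ids role configuration.
#' @param growth_fraction primary-target growth as a fraction of maximal
#'   growth (default 0.03).
#' @param n_mid number of interior target points (default 10).
#' @param max_knockouts knockout cap for retained alternative envelopes
#'   (default 10).
#' @param n_points envelope grid size (default 100).
#' @param cap_K optional integer vector of knockout budgets to evaluate on
#'   the primary envelope.
#' @param out_dir optional directory for TSV/JSON reports.
#' @return list with `model` (irreversible working model), `wild_envelope`,
#'   `primary_design`, `comparison` (a `comparison_table`), and `capped`
#'   (list of budget designs or `NULL`).
#' @export
run_strain_design <- function(model, product_id, biomass_id = NULL,
                              medium = NULL, maintenance_ids = character(),
                              diffusion_ids = character(),
                              growth_fraction = 0.03, n_mid = 10,
                              max_knockouts = 10, n_points = 100,
                              cap_K = NULL, out_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(medium)) medium <- read_medium_config(medium)
  if (!is.null(medium)) {
    maintenance_ids <- unique(c(maintenance_ids, medium$maintenance))
    diffusion_ids <- unique(c(diffusion_ids, medium$diffusion_transport))
    if (is.null(biomass_id)) biomass_id <- medium$biomass
    model <- apply_medium(model, medium)
  }
  if (is.null(biomass_id)) {
    nz <- model$rxn_ids[model$objective != 0]
    if (length(nz) != 1L) stop("cannot infer biomass reaction; pass biomass_id")
    biomass_id <- nz
  }
  if (!product_id %in% c(model$rxn_ids, unname(model$original_ids)))
    stop("product exchange '", product_id, "' not found in the model")
  if (all(model$roles == "internal"))
    model <- classify_roles(model, biomass_id, maintenance_ids, diffusion_ids)
  model <- to_irreversible(model)
  if (model$roles[biomass_id] != "biomass")
    model <- classify_roles(model, biomass_id, maintenance_ids, diffusion_ids)

  wt <- compute_envelope(model, biomass_id, product_id, n_points = n_points)
  comparison <- scan_targets(model, biomass_id, product_id,
                             n_mid = n_mid, max_knockouts = max_knockouts,
                             growth_fraction = growth_fraction,
                             n_points = n_points)
  designs <- attr(comparison, "designs")
  primary <- designs[[1]]

  capped <- NULL
  if (!is.null(cap_K)) {
    mar <- find_mar(model, attr(comparison, "primary"), biomass_id, product_id)
    protected <- source_ids(model, mar$active_set)
    capped <- cap_series(model, protected, cap_K, biomass_id, product_id)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    envelope_table(wt, file.path(out_dir, "wildtype_envelope.tsv"))
    envelope_table(primary$envelope, file.path(out_dir, "primary_envelope.tsv"))
    write_comparison(comparison,
                     tsv = file.path(out_dir, "comparison.tsv"),
                     json = file.path(out_dir, "comparison.json"))
    jsonlite::write_json(design_json(primary),
                         file.path(out_dir, "primary_design.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, biomass_id = biomass_id, product_id = product_id,
       wild_envelope = wt, primary_design = primary,
       comparison = comparison, capped = capped)
}

design_json <- function(d) {
  list(knockouts = d$knockouts, count = d$count,
       min_production = d$min_production, max_production = d$max_production,
       mp_growth = d$mp_growth, mp_production_min = d$mp_production_min,
       mp_production_max = d$mp_production_max, coupling = d$coupling,
       mar_objective = d$mar_objective,
       target = if (is.null(d$target)) NULL else unclass(d$target))
}

#' Compare candidate host organisms for one product
#'
#' Runs the pipeline per host and tabulates the primary-envelope metrics in
#' g/g substrate yield units, ranking hosts by coupling strength, then
#' fewer knockouts, then higher minimum yield.
#'
#' @param hosts list of host specifications; each a list with `name`,
#'   `model` (object or path), `product_id`, optional `biomass_id`,
#'   `medium`, `maintenance_ids`, `diffusion_ids`, `product_mw` (g/mol),
#'   `substrate_mw` (g/mol, default glucose 180.16), `substrate_uptake`
#'   (mmol/gDCW/h, default 10).
#' @param ... passed to [run_strain_design()].
#' @return data frame, one row per host, ranked; full pipeline results in
#'   `attr(, "runs")`.
#' @export
compare_hosts <- function(hosts, ...) {
  rows <- list(); runs <- list()
  for (h in hosts) {
    run <- run_strain_design(h$model, h$product_id, biomass_id = h$biomass_id,
                             medium = h$medium,
                             maintenance_ids = h$maintenance_ids %||% character(),
                             diffusion_ids = h$diffusion_ids %||% character(),
                             ...)
    d <- run$primary_design
    up <- h$substrate_uptake %||% 10
    smw <- (h$substrate_mw %||% 180.16) / 1000
    pmw <- (h$product_mw %||% 1000) / 1000
    rows[[length(rows) + 1L]] <- data.frame(
      host = h$name %||% run$model$id,
      coupling = d$coupling,
      knockouts = d$count,
      min_yield = to_yield_units(d$min_production, pmw, up, smw),
      max_yield = to_yield_units(d$max_production, pmw, up, smw),
      mp_yield = to_yield_units(d$mp_production_max, pmw, up, smw),
      mp_growth_yield = to_yield_units(d$mp_growth, 1, up, smw),  # gDCW per mmol "biomass"
      stringsAsFactors = FALSE)
    runs[[length(runs) + 1L]] <- run
  }
  df <- do.call(rbind, rows)
  rank_key <- order(match(df$coupling, c("strong", "weak", "none")),
                    df$knockouts, -df$min_yield)
  df <- df[rank_key, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, runs = runs[rank_key])
}
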