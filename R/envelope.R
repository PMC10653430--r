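# Flux balance analysis and the product-versus-growth production envelope.
#
# The envelope is built the standard way: compute the minimum and maximum
# feasible growth, lay a grid of growth values across that range (100 points
# including the endpoints by default), and at each grid value fix the
# biomass flux and minimise/maximise the product exchange flux by LP.
# Coupling strength is read off the zero-growth edge: if the minimum
# secretion without growth is positive the design is strongly coupled.

ZERO_FLUX_TOL <- 1e-9       # |v| above this counts as carrying flux
COUPLING_TOL  <- 1e-6       # mmol/gDCW/h; minimum-secretion threshold

#' Flux balance analysis
#'
#' Optimise a single reaction flux (or the model objective) over the
#' steady-state polytope `S v = 0`, `lb <= v <= ub`, optionally with
#' additional equality fixings.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction id to optimise; `NULL` uses the model's
#'   objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @param fixed named numeric vector of reaction fluxes to fix (equality).
#' @return list with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   and named flux vector `fluxes` (`NA` when infeasible).
#' @export
fba <- function(model, objective_id = NULL, sense = c("max", "min"),
                fixed = NULL) {
  sense <- match.arg(sense)
  n <- n_reactions(model)
  obj <- if (is.null(objective_id)) unname(model$objective) else {
    o <- numeric(n); o[rxn_index(model, objective_id)] <- 1; o
  }
  lb <- unname(model$lower); ub <- unname(model$upper)
  if (length(fixed)) {
    i <- rxn_index(model, names(fixed))
    lo <- pmax(lb[i], as.numeric(fixed)); hi <- pmin(ub[i], as.numeric(fixed))
    if (any(lo > hi + 1e-9))
      return(list(status = "infeasible", objective = NA_real_,
                  fluxes = stats::setNames(rep(NA_real_, n), model$rxn_ids)))
    lb[i] <- lo; ub[i] <- hi
  }
  res <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, n_metabolites(model)),
                  lower = lb, upper = ub, sense = sense)
  if (res$status != "optimal")
    return(list(status = "infeasible", objective = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), model$rxn_ids)))
  list(status = "optimal", objective = res$objective,
       fluxes = stats::setNames(res$x, model$rxn_ids))
}

# min and max of one flux with biomass pinned to g; NA pair when infeasible
product_range_at <- function(model, biomass_id, product_id, g) {
  f <- stats::setNames(g, biomass_id)
  lo <- fba(model, product_id, "min", fixed = f)
  if (lo$status != "optimal") return(c(NA_real_, NA_real_))
  hi <- fba(model, product_id, "max", fixed = f)
  c(lo$objective, hi$objective)
}

#' Compute the production envelope
#'
#' @param model a `metabolic_model`.
#' @param biomass_id,product_id reaction ids of the biomass reaction and the
#'   product exchange.
#' @param n_points number of growth grid points including endpoints
#'   (default 100).
#' @param tol coupling tolerance (mmol/gDCW/h).
#' @return object of class `production_envelope` with fields `growth_grid`,
#'   `min_product`, `max_product`, `max_growth`, `mp_point`,
#'   `min_production_at_zero_growth` and `coupling`.
#' @export
compute_envelope <- function(model, biomass_id, product_id, n_points = 100,
                             tol = COUPLING_TOL) {
  stopifnot(n_points >= 2)
  gmax <- fba(model, biomass_id, "max")
  gmin <- fba(model, biomass_id, "min")
  if (gmax$status != "optimal" || gmin$status != "optimal")
    stop("model infeasible: cannot compute growth range")
  grid <- seq(gmin$objective, gmax$objective, length.out = n_points)
  pr <- vapply(grid, function(g)
    product_range_at(model, biomass_id, product_id, g), numeric(2))
  # zero-growth minimum secretion: the strong-coupling statistic
  p0 <- if (gmin$objective <= tol) {
    product_range_at(model, biomass_id, product_id, max(gmin$objective, 0))[1]
  } else NA_real_
  mp <- product_range_at(model, biomass_id, product_id, gmax$objective)
  env <- structure(list(
    biomass_id = biomass_id, product_id = product_id,
    growth_grid = grid,
    min_product = pr[1, ], max_product = pr[2, ],
    max_growth = gmax$objective, min_growth = gmin$objective,
    mp_point = c(growth = gmax$objective, min_product = mp[1],
                 max_product = mp[2]),
    min_production_at_zero_growth = p0,
    tol = tol
  ), class = "production_envelope")
  env$coupling <- classify_coupling(env, tol)
  env
}

#' Classify coupling strength of an envelope
#'
#' Strong: the minimum secretion rate without growth is positive (above
#' `tol`).  Weak: the minimum secretion is positive somewhere on the grid
#' but not at zero growth.  None: the product is never obligatory.  A model
#' that cannot reach zero growth at all is classified from the minimum
#' secretion at its lowest feasible growth.
#'
#' @param env a `production_envelope`.
#' @param tol threshold in mmol/gDCW/h (default `1e-6`).
#' @return `"strong"`, `"weak"` or `"none"`.
#' @export
classify_coupling <- function(env, tol = COUPLING_TOL) {
  p0 <- env$min_production_at_zero_growth
  if (is.na(p0)) p0 <- env$min_product[1]      # zero growth infeasible
  if (isTRUE(p0 > tol)) return("strong")
  if (any(env$min_product > tol, na.rm = TRUE)) return("weak")
  "none"
}

#' Most probable operating point
#'
#' Under adaptive laboratory evolution the fastest-growing mutants take
#' over, so the envelope point of maximal growth is the expected operating
#' point.  Returns that growth rate together with the minimum and maximum
#' product rate there (they coincide for strongly coupled designs).
#'
#' @inheritParams compute_envelope
#' @return named numeric `(growth, min_product, max_product)`.
#' @export
mp_point <- function(model, biomass_id, product_id) {
  g <- fba(model, biomass_id, "max")
  if (g$status != "optimal") stop("model infeasible: no maximal growth")
  pr <- product_range_at(model, biomass_id, product_id, g$objective)
  c(growth = g$objective, min_product = pr[1], max_product = pr[2])
}

#' Convert a secretion rate to a g/g substrate yield
#'
#' `rate * mw / (substrate_uptake * substrate_mw)`.  For biomass, pass the
#' growth rate (1/h) with `molecular_weight = 1`: gDCW produced per gram of
#' substrate.
#'
#' @param rate secretion rate, mmol/gDCW/h (or growth rate, 1/h).
#' @param molecular_weight product weight, g/mmol.
#' @param substrate_uptake substrate uptake rate, mmol/gDCW/h (> 0).
#' @param substrate_weight substrate weight, g/mmol.
#' @return yield in g product per g substrate.
#' @export
to_yield_units <- function(rate, molecular_weight, substrate_uptake,
                           substrate_weight) {
  if (substrate_uptake <= 0) stop("substrate uptake must be > 0")
  rate * molecular_weight / (substrate_uptake * substrate_weight)
}

#' Molecular weights shipped with the package (g/mol)
#'
#' Weights of the substrates/products used in the host-comparison workflow.
#' @return named numeric vector.
#' @export
molecular_weights <- function() {
  c(glucose = 180.16, acetate = 60.05, glycerol = 92.09,
    ethanol = 46.07, succinate = 118.09)
}

#' @export
print.production_envelope <- function(x, ...) {
  cat("<production_envelope> ", x$product_id, " vs ", x$biomass_id, "\n", sep = "")
  cat(sprintf("  growth range: [%.6g, %.6g] 1/h over %d grid points\n",
              x$min_growth, x$max_growth, length(x$growth_grid)))
  cat(sprintf("  MP point: growth %.6g, product [%.6g, %.6g]\n",
              x$mp_point[["growth"]], x$mp_point[["min_product"]],
              x$mp_point[["max_product"]]))
  cat(sprintf("  min production at zero growth: %s\n",
              format(x$min_production_at_zero_growth)))
  cat("  coupling:", x$coupling, "\n")
  invisible(x)
}

#' Export an envelope as a data frame / TSV
#'
#' @param env a `production_envelope`.
#' @param path optional TSV output path.
#' @return data frame with columns `growth`, `min_product`, `max_product`.
#' @export
envelope_table <- function(env, path = NULL) {
  df <- data.frame(growth = env$growth_grid,
                   min_product = env$min_product,
                   max_product = env$max_product)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}

#' Plot one or more production envelopes
#'
#' @param env a `production_envelope` or list of them.
#' @param col line colours, recycled.
#' @param labels legend labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_envelope <- function(env, col = c("steelblue", "firebrick", "darkgreen"),
                          labels = NULL, ...) {
  envs <- if (inherits(env, "production_envelope")) list(env) else env
  col <- rep_len(col, length(envs))
  xm <- max(vapply(envs, function(e) e$max_growth, numeric(1)))
  ym <- max(vapply(envs, function(e) max(e$max_product, na.rm = TRUE), numeric(1)))
  graphics::plot(NA, xlim = c(0, xm * 1.02), ylim = c(0, ym * 1.05),
                 xlab = "growth rate (1/h)",
                 ylab = "product secretion (mmol/gDCW/h)", ...)
  for (k in seq_along(envs)) {
    e <- envs[[k]]
    ok <- !is.na(e$min_product)
    graphics::polygon(c(e$growth_grid[ok], rev(e$growth_grid[ok])),
                      c(e$min_product[ok], rev(e$max_product[ok])),
                      border = col[k], col = grDevices::adjustcolor(col[k], 0.15))
  }
  if (!is.null(labels))
    graphics::legend("topright", legend = labels, col = col, lty = 1, bty = "n")
  invisible(NULL)
}
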