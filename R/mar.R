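# Minimal active reactions (MAR) at a target point.
#
# Each non-exempt reaction j gets a binary activity indicator z_j with
# v_j - v_j,max * z_j <= 0, so z_j = 0 forces the (irreversible) flux to
# zero.  Exchanges and diffusion-based protein-free transports carry no
# indicator at all (they are not enzymatic); the biomass and maintenance
# reactions carry an indicator that is fixed to 1, so they count towards
# the objective but can never be removed.  Minimising the sum of z over a
# flux distribution pinned to the target point yields the smallest set of
# enzymatic reactions able to operate there.  For split reversible pairs
# z_f + z_b <= 1 forbids futile two-way cycles.

#' Create a target point
#'
#' @param growth_rate growth rate, 1/h.
#' @param production_rate product secretion, mmol/gDCW/h.
#' @param growth_fraction optional fraction of wild-type maximal growth this
#'   point corresponds to (metadata).
#' @param edge `"upper_edge"` or `"interior"`.
#' @return object of class `target_point`.
#' @export
target_point <- function(growth_rate, production_rate,
                         growth_fraction = NA_real_,
                         edge = c("upper_edge", "interior")) {
  edge <- match.arg(edge)
  structure(list(growth_rate = growth_rate,
                 production_rate = production_rate,
                 growth_fraction = growth_fraction, edge = edge),
            class = "target_point")
}

#' Primary target point on the upper edge
#'
#' The default primary target sits on the maximum-production boundary at a
#' small fraction of the wild-type maximal growth (default 3%): high
#' production with low but nonzero growth, where by-product secretion is
#' minimal.
#'
#' @param model irreversible `metabolic_model`.
#' @param biomass_id,product_id reaction ids.
#' @param growth_fraction fraction of maximal growth (default 0.03).
#' @return a `target_point`.
#' @export
primary_target <- function(model, biomass_id, product_id,
                           growth_fraction = 0.03) {
  g <- fba(model, biomass_id, "max")
  if (g$status != "optimal") stop("model infeasible")
  gt <- growth_fraction * g$objective
  pr <- product_range_at(model, biomass_id, product_id, gt)
  if (anyNA(pr)) stop("target growth infeasible")
  target_point(gt, pr[2], growth_fraction, "upper_edge")
}

# reactions that receive an activity indicator, and which of those are
# frozen active (never knockout candidates)
mar_indicator_sets <- function(model) {
  has_z <- !(model$roles %in% c("exchange", "diffusion_transport"))
  frozen <- model$roles %in% c("biomass", "maintenance")
  list(z_ids = model$rxn_ids[has_z], frozen = model$rxn_ids[has_z & frozen])
}

#' Find the minimal active reaction set at a target point
#'
#' Solves the MILP: minimise the number of active non-exempt reactions
#' subject to steady state, flux bounds, the activity linking constraints,
#' one-direction-at-a-time constraints for split pairs, and the biomass and
#' product fluxes pinned to the target (equality within `target_tol`).
#'
#' @param model irreversible `metabolic_model` with roles classified.
#' @param target a `target_point` (or numeric `c(growth, production)`).
#' @param biomass_id,product_id reaction ids.
#' @param target_tol half-width of the equality window on the two target
#'   fluxes (default `1e-6`).
#' @return object of class `mar_result`: binary vector `z` (named), the
#'   `active_set` (z = 1 plus exempt reactions), the `removed_set` (z = 0),
#'   and `objective` (number of active indicator-carrying reactions).
#' @export
find_mar <- function(model, target, biomass_id, product_id,
                     target_tol = 1e-6) {
  if (!inherits(target, "target_point"))
    target <- target_point(target[1], target[2])
  validate_model(model, irreversible = TRUE)
  sets <- mar_indicator_sets(model)
  zi <- rxn_index(model, sets$z_ids)
  n <- n_reactions(model); k <- length(zi)

  lb <- unname(model$lower); ub <- unname(model$upper)
  ub0 <- ub                               # v_max before target pinning
  bi <- rxn_index(model, biomass_id); pi <- rxn_index(model, product_id)
  lb[bi] <- target$growth_rate - target_tol
  ub[bi] <- min(ub[bi], target$growth_rate + target_tol)
  lb[pi] <- target$production_rate - target_tol
  ub[pi] <- min(ub[pi], target$production_rate + target_tol)
  lb[bi] <- max(lb[bi], 0); lb[pi] <- max(lb[pi], 0)

  zl <- rep(0, k); zu <- rep(1, k)
  zl[sets$z_ids %in% sets$frozen] <- 1

  # linking rows v_j - ub_j z_j <= 0
  A1 <- matrix(0, k, n + k)
  for (t in seq_len(k)) {
    A1[t, zi[t]] <- 1
    vmax <- ub0[zi[t]]
    if (!is.finite(vmax)) vmax <- 1000   # "unbounded" convention
    A1[t, n + t] <- -max(vmax, 1)
  }
  # split pairs among indicator carriers: z_f + z_b <= 1
  pair_rows <- list()
  for (f in names(model$rev_pairs)) {
    b <- model$rev_pairs[[f]]
    tf <- match(f, sets$z_ids); tb <- match(b, sets$z_ids)
    if (is.na(tf) || is.na(tb)) next
    row <- numeric(n + k); row[n + tf] <- 1; row[n + tb] <- 1
    pair_rows[[length(pair_rows) + 1L]] <- row
  }
  A2 <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  A_le <- rbind(A1, A2)
  b_le <- rep(0, nrow(A1))
  if (!is.null(A2)) b_le <- c(b_le, rep(1, nrow(A2)))

  res <- milp_solve(c(rep(0, n), rep(1, k)),
                    A_eq = cbind(model$S, matrix(0, n_metabolites(model), k)),
                    b_eq = rep(0, n_metabolites(model)),
                    A_le = A_le, b_le = b_le,
                    lower = c(lb, zl), upper = c(ub, zu),
                    int_idx = n + seq_len(k))
  if (res$status != "optimal")
    stop("target point (", signif(target$growth_rate, 6), ", ",
         signif(target$production_rate, 6), ") is ",
         if (res$status == "infeasible") "infeasible" else res$status)
  z <- stats::setNames(round(res$x[n + seq_len(k)]), sets$z_ids)
  removed <- sets$z_ids[z == 0]
  active <- c(sets$z_ids[z == 1],
              model$rxn_ids[!(model$rxn_ids %in% sets$z_ids)])
  structure(list(z = z,
                 active_set = model$rxn_ids[model$rxn_ids %in% active],
                 removed_set = removed,
                 objective = sum(z),
                 target = target,
                 fluxes = stats::setNames(res$x[seq_len(n)], model$rxn_ids)),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat("<mar_result> ", x$objective, " active indicator reactions; ",
      length(x$removed_set), " removed\n", sep = "")
  cat("  target: growth", signif(x$target$growth_rate, 6), ", production",
      signif(x$target$production_rate, 6), "\n")
  invisible(x)
}

#' Bound all non-MAR reactions to zero
#'
#' @param model the model `find_mar()` was run on.
#' @param mar a `mar_result`.
#' @return reduced model (removed reactions have both bounds zero).
#' @export
reduce_to_mar <- function(model, mar) {
  if (length(mar$removed_set) == 0L) return(model)
  model$lower[mar$removed_set] <- 0
  model$upper[mar$removed_set] <- 0
  model
}

#' Serialise a MAR result to JSON
#' @param mar a `mar_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mar_json <- function(mar, path) {
  jsonlite::write_json(list(
    objective = mar$objective,
    target = unclass(mar$target),
    active_set = mar$active_set,
    removed_set = mar$removed_set
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
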