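# Synthetic toy networks with hand-derivable envelopes, plus brute-force
# oracles for the two MILPs.  The toys go through the same model container
# and I/O as real models, so they exercise the full pipeline offline.

#' Five-metabolite coupling toy
#'
#' Substrate A enters through `EX_A` (upper bound `substrate_ub`) and can
#' reach the carbon sink C three ways: via `R2` (which co-produces the
#' product P), via the bypass `R5`, or not at all.  Biomass `R3` consumes
#' B + C; `ATPM` is a maintenance drain on C with a positive lower bound.
#' With defaults the wild type has maximal growth 4.5 1/h, maximum product
#' `10 - g`, minimum 0 everywhere; knocking out `R5` makes the product
#' obligatory (`min = g + 1`), i.e. strong coupling.
#'
#' @param maintenance_lb lower bound of `ATPM` (default 1); set 0 to make
#'   the `R5` knockout only weakly coupled.
#' @param substrate_ub uptake bound of `EX_A` (default 10).
#' @return irreversible `metabolic_model` with roles classified and the
#'   biomass objective set.
#' @export
make_coupling_toy <- function(maintenance_lb = 1, substrate_ub = 10) {
  mets <- c("A", "B", "C", "P", "BM")
  rxns <- c("EX_A", "R1", "R2", "R5", "R3", "ATPM", "EX_P", "EX_BM")
  S <- matrix(0, 5, 8, dimnames = list(mets, rxns))
  S["A", "EX_A"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["A", "R2"] <- -1; S["P", "R2"] <- 1; S["C", "R2"] <- 1
  S["A", "R5"] <- -1; S["C", "R5"] <- 1
  S["B", "R3"] <- -1; S["C", "R3"] <- -1; S["BM", "R3"] <- 1
  S["C", "ATPM"] <- -1
  S["P", "EX_P"] <- -1
  S["BM", "EX_BM"] <- -1
  lb <- c(0, 0, 0, 0, 0, maintenance_lb, 0, 0)
  ub <- c(substrate_ub, 1000, 1000, 1000, 1000, 1000, 1000, 1000)
  obj <- as.numeric(rxns == "R3")
  mdl <- metabolic_model(S, lb, ub, obj, id = "coupling_toy")
  classify_roles(mdl, biomass_id = "R3", maintenance_ids = "ATPM")
}

#' Branched coupling toy
#'
#' Extends [make_coupling_toy()] with two extra internal routes: `R4`
#' (B -> C, a second product-free path to the carbon sink) and `R6`
#' (A -> P, product without feeding C).  Strong coupling now needs the two
#' bypasses `R4` and `R5` removed, which gives the knockout-budget solver
#' and the scan something non-trivial to do.
#'
#' @inheritParams make_coupling_toy
#' @return irreversible `metabolic_model`.
#' @export
make_branched_toy <- function(maintenance_lb = 1, substrate_ub = 10) {
  mets <- c("A", "B", "C", "P", "BM")
  rxns <- c("EX_A", "R1", "R2", "R5", "R4", "R6", "R3", "ATPM", "EX_P", "EX_BM")
  S <- matrix(0, 5, 10, dimnames = list(mets, rxns))
  S["A", "EX_A"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["A", "R2"] <- -1; S["P", "R2"] <- 1; S["C", "R2"] <- 1
  S["A", "R5"] <- -1; S["C", "R5"] <- 1
  S["B", "R4"] <- -1; S["C", "R4"] <- 1
  S["A", "R6"] <- -1; S["P", "R6"] <- 1
  S["B", "R3"] <- -1; S["C", "R3"] <- -1; S["BM", "R3"] <- 1
  S["C", "ATPM"] <- -1
  S["P", "EX_P"] <- -1
  S["BM", "EX_BM"] <- -1
  lb <- c(0, 0, 0, 0, 0, 0, 0, maintenance_lb, 0, 0)
  ub <- c(substrate_ub, rep(1000, 9))
  obj <- as.numeric(rxns == "R3")
  mdl <- metabolic_model(S, lb, ub, obj, id = "branched_toy")
  classify_roles(mdl, biomass_id = "R3", maintenance_ids = "ATPM")
}

#' Toy with a reversible internal reaction
#'
#' Adds a reversible shunt `RBC: B <-> C` to the coupling toy, so
#' conversion to irreversible form splits it into a forward/backward pair.
#' (The shunt is chosen so no direction closes a mass-creating cycle.)
#' Its forward direction is a second product-free route to the carbon
#' sink, so strong coupling needs both `R5` and `RBC` knocked out.
#' Exercises the split bookkeeping and the one-direction-at-a-time MILP
#' constraint.
#'
#' @inheritParams make_coupling_toy
#' @return reversible-form `metabolic_model` (run [to_irreversible()]).
#' @export
make_reversible_toy <- function(maintenance_lb = 1, substrate_ub = 10) {
  mdl <- make_coupling_toy(maintenance_lb, substrate_ub)
  rbc <- numeric(n_metabolites(mdl))
  names(rbc) <- mdl$met_ids
  rbc["B"] <- -1; rbc["C"] <- 1
  S2 <- cbind(mdl$S, RBC = rbc)
  mdl2 <- metabolic_model(S2, c(mdl$lower, -1000), c(mdl$upper, 1000),
                          c(mdl$objective, 0), id = "reversible_toy")
  classify_roles(mdl2, biomass_id = "R3", maintenance_ids = "ATPM")
}

#' Brute-force minimal-active-reaction oracle
#'
#' Enumerates every activity pattern over the non-frozen indicator-carrying
#' reactions, checks LP feasibility at the target under each (removed
#' reactions bounded to zero, target fluxes pinned), and returns the
#' minimum active count with every optimal active set.  Patterns activating
#' both directions of a split pair are excluded, matching the MILP's pair
#' constraint.
#'
#' @param model irreversible `metabolic_model` with roles classified.
#' @param target a `target_point` or numeric `c(growth, production)`.
#' @param biomass_id,product_id reaction ids.
#' @param target_tol equality window (matches [find_mar()]).
#' @param max_candidates refuse larger enumerations (default 15).
#' @return list with `feasible` (logical), `min_count`, and `optimal_sets`
#'   (list of character vectors: active indicator reactions).
#' @export
brute_force_mar <- function(model, target, biomass_id, product_id,
                            target_tol = 1e-6, max_candidates = 15) {
  if (!inherits(target, "target_point"))
    target <- target_point(target[1], target[2])
  sets <- mar_indicator_sets(model)
  cand <- setdiff(sets$z_ids, sets$frozen)
  if (length(cand) > max_candidates)
    stop("too many candidate reactions for enumeration: ", length(cand))
  pairs <- model$rev_pairs[names(model$rev_pairs) %in% cand &
                             unlist(model$rev_pairs) %in% cand]

  lb <- unname(model$lower); ub <- unname(model$upper)
  bi <- rxn_index(model, biomass_id); pj <- rxn_index(model, product_id)
  lb[bi] <- max(lb[bi], target$growth_rate - target_tol)
  ub[bi] <- min(ub[bi], target$growth_rate + target_tol)
  lb[pj] <- max(lb[pj], target$production_rate - target_tol)
  ub[pj] <- min(ub[pj], target$production_rate + target_tol)

  feasible_with <- function(active) {
    off <- rxn_index(model, setdiff(cand, active))
    l <- lb; u <- ub
    l[off] <- pmax(l[off], 0); u[off] <- pmin(u[off], 0)
    if (any(l > u + 1e-12)) return(FALSE)
    r <- lp_solve(numeric(length(l)), A_eq = model$S,
                  b_eq = rep(0, n_metabolites(model)), lower = l, upper = u)
    r$status == "optimal"
  }

  best <- Inf; optima <- list()
  nc <- length(cand)
  for (mask in 0:(2^nc - 1)) {
    active <- cand[bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0]
    if (length(pairs) &&
        any(names(pairs) %in% active & unlist(pairs) %in% active)) next
    count <- length(active) + length(sets$frozen)
    if (count > best) next
    if (!feasible_with(active)) next
    full <- sort(c(active, sets$frozen))
    if (count < best) { best <- count; optima <- list(full) }
    else optima <- c(optima, list(full))
  }
  list(feasible = is.finite(best),
       min_count = if (is.finite(best)) best else NA_integer_,
       optimal_sets = optima)
}

#' Brute-force knockout-budget oracle
#'
#' Exhaustive search over all candidate knockout subsets of size `<= K`
#' with an LP inner solve per subset; same contract as [cap_knockouts()].
#' Deterministic tie-break: smaller subsets first, then lexicographic.
#'
#' @inheritParams cap_knockouts
#' @return list with `knockouts`, `certified_min`.
#' @export
brute_force_cap <- function(model, protected, K, biomass_id, product_id) {
  exempt_roles <- c("exchange", "diffusion_transport", "biomass", "maintenance")
  cand_dirs <- model$rxn_ids[!(model$roles %in% exempt_roles) &
                               !(unname(model$original_ids[model$rxn_ids]) %in% protected)]
  cand <- sort(unique(unname(model$original_ids[cand_dirs])))
  K <- min(K, length(cand))
  inner_min <- function(ko) {
    r <- fba(knockout(model, ko), product_id, "min",
             fixed = stats::setNames(0, biomass_id))
    if (r$status == "optimal") r$objective else -Inf
  }
  best_val <- -Inf; best_ko <- character()
  for (k in 0:K) {
    subsets <- if (k == 0) list(character()) else
      utils::combn(cand, k, simplify = FALSE)
    for (ko in subsets) {
      v <- inner_min(ko)
      if (v > best_val + 1e-9) { best_val <- v; best_ko <- ko }
    }
  }
  list(knockouts = best_ko, certified_min = best_val)
}
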