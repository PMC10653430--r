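# The constraint-based model container used throughout the package.
#
# A metabolic_model is a plain list: dense stoichiometric matrix S (m x n,
# metabolites x reactions), named flux bounds in mmol/gDCW/h, linear
# objective coefficients, a role label per reaction, and the bookkeeping
# needed after reversible reactions are split (forward/backward pairs and the
# map back to the source reaction id).

#' Construct a metabolic model
#'
#' @param S stoichiometric matrix (metabolites x reactions); dimnames are
#'   used as metabolite and reaction ids when `met_ids`/`rxn_ids` are absent.
#' @param lower,upper flux bounds per reaction (mmol/gDCW/h).
#' @param objective linear objective coefficients per reaction.
#' @param met_ids,rxn_ids identifier vectors.
#' @param roles character vector per reaction, each one of `"exchange"`,
#'   `"diffusion_transport"`, `"biomass"`, `"maintenance"`, `"internal"`.
#' @param rev_pairs named character vector mapping forward reaction id to its
#'   backward partner id (empty for unsplit models).
#' @param original_ids named character vector mapping split reaction ids to
#'   their source reversible reaction id.
#' @param id model identifier string.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lower, upper, objective = NULL,
                            met_ids = rownames(S), rxn_ids = colnames(S),
                            roles = NULL, rev_pairs = character(),
                            original_ids = NULL, id = "model") {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  if (is.null(met_ids) || is.null(rxn_ids))
    stop("metabolite and reaction ids are required")
  met_ids <- as.character(met_ids); rxn_ids <- as.character(rxn_ids)
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids: ",
                                   paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  stopifnot(length(met_ids) == m, length(rxn_ids) == n,
            length(lower) == n, length(upper) == n)
  dimnames(S) <- list(met_ids, rxn_ids)
  objective <- if (is.null(objective)) rep(0, n) else as.numeric(objective)
  stopifnot(length(objective) == n)
  roles <- if (is.null(roles)) rep("internal", n) else as.character(roles)
  stopifnot(length(roles) == n)
  bad <- setdiff(roles, c("exchange", "diffusion_transport", "biomass",
                          "maintenance", "internal"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  if (is.null(original_ids)) original_ids <- stats::setNames(rxn_ids, rxn_ids)
  structure(list(
    id = id,
    met_ids = met_ids, rxn_ids = rxn_ids, S = S,
    lower = stats::setNames(as.numeric(lower), rxn_ids),
    upper = stats::setNames(as.numeric(upper), rxn_ids),
    objective = stats::setNames(objective, rxn_ids),
    roles = stats::setNames(roles, rxn_ids),
    rev_pairs = rev_pairs,
    original_ids = original_ids
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", length(x$met_ids), " metabolites x ",
      length(x$rxn_ids), " reactions\n", sep = "")
  tab <- table(x$roles)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$rev_pairs))
    cat("  split reversible pairs:", length(x$rev_pairs), "\n")
  if (any(x$objective != 0))
    cat("  objective:", paste(x$rxn_ids[x$objective != 0], collapse = ", "), "\n")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) length(model$rxn_ids)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) length(model$met_ids)

rxn_index <- function(model, ids, what = "reaction") {
  i <- match(ids, model$rxn_ids)
  if (anyNA(i)) stop("unknown ", what, " id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  i
}

#' Map split reaction ids to all directions of their source reaction
#'
#' Given reaction ids at either the split (directional) or the source
#' (reversible) level, return every split column belonging to the same
#' source reactions.  Used so a knockout always removes both directions.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids (split or source level).
#' @return character vector of split reaction ids.
#' @export
expand_directions <- function(model, ids) {
  src <- ifelse(ids %in% model$rxn_ids, unname(model$original_ids[ids]), ids)
  known <- unique(c(model$rxn_ids, unname(model$original_ids)))
  bad <- setdiff(src, known)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  model$rxn_ids[model$original_ids[model$rxn_ids] %in% src]
}

#' Knock out reactions (both directions of split pairs)
#'
#' Deletion is modelled by setting both flux bounds to zero, matching enzyme
#' removal; ids may be given at the source (reversible) level.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to remove.
#' @return modified model.
#' @export
knockout <- function(model, ids) {
  if (length(ids) == 0L) return(model)
  cols <- expand_directions(model, ids)
  model$lower[cols] <- 0
  model$upper[cols] <- 0
  model
}

#' Restore reaction bounds from a reference model
#'
#' Inverse of [knockout()]: copies the bounds of every direction of `ids`
#' from `reference` (typically the pre-reduction model).
#'
#' @param model model with reactions bound to zero.
#' @param reference model holding the original bounds.
#' @param ids reaction ids (source or split level).
#' @return modified model.
#' @export
restore_reactions <- function(model, reference, ids) {
  cols <- expand_directions(model, ids)
  model$lower[cols] <- reference$lower[cols]
  model$upper[cols] <- reference$upper[cols]
  model
}

#' Reaction ids by role
#' @param model a `metabolic_model`.
#' @param role one of the role labels.
#' @return character vector of reaction ids.
#' @export
reactions_by_role <- function(model, role) {
  model$rxn_ids[model$roles == role]
}

#' Validate model invariants
#'
#' Checks the structural invariants assumed by the optimisation code:
#' non-negative lower bounds once split, exact column negation of
#' forward/backward pairs, a single biomass reaction.
#'
#' @param model a `metabolic_model`.
#' @param irreversible require all lower bounds `>= 0`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_model <- function(model, irreversible = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (irreversible && any(model$lower < 0))
    stop("model is not irreversible: negative lower bounds on ",
         paste(model$rxn_ids[model$lower < 0], collapse = ", "))
  if (any(model$lower > model$upper))
    stop("lower bound exceeds upper bound")
  for (f in names(model$rev_pairs)) {
    b <- model$rev_pairs[[f]]
    if (max(abs(model$S[, f] + model$S[, b])) > 1e-12)
      stop("split pair ", f, "/", b, " columns are not exact negatives")
  }
  bio <- model$rxn_ids[model$roles == "biomass"]
  if (length(unique(unname(model$original_ids[bio]))) > 1L)
    stop("more than one biomass reaction")
  invisible(TRUE)
}
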