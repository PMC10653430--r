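# Reversible reactions are split into separate forward and backward columns
# before any optimisation: the activity-indicator MILP needs every flux to be
# non-negative so that v_j <= v_j,max * z_j switches a reaction off.

REV_SUFFIX <- "__rev"

#' Convert a model to irreversible form
#'
#' Every reaction with a negative lower bound is split into a forward
#' reaction (original id, bounds `[0, max(ub, 0)]`) and a backward reaction
#' (id suffixed with `"__rev"`, negated column, bounds `[0, -lb]`).  A
#' reaction that can only run backwards (`ub <= 0`) is flipped in place and
#' given the suffix, with no forward partner.  Objective coefficients are
#' negated on backward columns so any linear objective keeps its optimum.
#' Applying the operation twice is the identity.
#'
#' @param model a `metabolic_model`.
#' @return irreversible `metabolic_model` with `rev_pairs`/`original_ids`
#'   populated.
#' @export
to_irreversible <- function(model) {
  if (all(model$lower >= 0)) return(model)
  cols <- list(); lbs <- c(); ubs <- c(); objs <- c(); roles <- c()
  ids <- c(); orig <- c(); pairs <- character()
  for (j in seq_along(model$rxn_ids)) {
    id <- model$rxn_ids[j]; lb <- model$lower[j]; ub <- model$upper[j]
    src <- unname(model$original_ids[id])
    if (lb >= 0) {
      cols[[length(cols) + 1L]] <- model$S[, j]
      ids <- c(ids, id); lbs <- c(lbs, lb); ubs <- c(ubs, ub)
      objs <- c(objs, model$objective[j]); roles <- c(roles, model$roles[j])
      orig <- c(orig, src)
    } else if (ub <= 0) {
      # runs backwards only: flip in place
      bid <- paste0(id, REV_SUFFIX)
      cols[[length(cols) + 1L]] <- -model$S[, j]
      ids <- c(ids, bid); lbs <- c(lbs, -ub); ubs <- c(ubs, -lb)
      objs <- c(objs, -model$objective[j]); roles <- c(roles, model$roles[j])
      orig <- c(orig, src)
    } else {
      bid <- paste0(id, REV_SUFFIX)
      cols[[length(cols) + 1L]] <- model$S[, j]
      cols[[length(cols) + 1L]] <- -model$S[, j]
      ids <- c(ids, id, bid)
      lbs <- c(lbs, 0, 0); ubs <- c(ubs, ub, -lb)
      objs <- c(objs, model$objective[j], -model$objective[j])
      roles <- c(roles, model$roles[j], model$roles[j])
      orig <- c(orig, src, src)
      pairs[id] <- bid
    }
  }
  S2 <- do.call(cbind, cols)
  colnames(S2) <- ids
  metabolic_model(S2, lbs, ubs, objs, met_ids = model$met_ids, rxn_ids = ids,
                  roles = unname(roles),
                  rev_pairs = c(model$rev_pairs, pairs),
                  original_ids = stats::setNames(unname(orig), ids),
                  id = model$id)
}

#' Is the model in irreversible form?
#' @param model a `metabolic_model`.
#' @return logical.
#' @export
is_irreversible <- function(model) all(model$lower >= 0)

#' Collapse split reaction ids to source reaction ids
#'
#' @param model a `metabolic_model`.
#' @param ids split-level reaction ids.
#' @return unique source-level ids, in first-appearance order.
#' @export
source_ids <- function(model, ids) {
  unique(unname(model$original_ids[ids]))
}
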