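# Growth-medium setup and reaction role classification.
#
# Exchange reactions are pseudo-reactions with a single nonzero
# stoichiometric entry.  The uptake direction of an exchange is whichever
# flux direction produces its metabolite inside the system: for the common
# `met ->` convention (entry -1) uptake is negative flux, so an uptake bound
# of 10 becomes lower bound -10; for `-> met` (entry +1) it becomes upper
# bound +10.

#' Apply a growth medium to a model
#'
#' Sets the substrate uptake bound (default 10 mmol/gDCW/h), opens the
#' listed freely available exchanges to 1000, closes the uptake direction of
#' every other exchange, and applies the aerobic/anaerobic setting: either
#' the oxygen exchange uptake is bound to zero, or the named reactions
#' (e.g. cytochrome c oxidase) are deleted when tiny oxygen amounts must
#' remain available for biomass.
#'
#' The product exchange (if named) keeps its secretion direction open and
#' has uptake closed like any unlisted exchange.
#'
#' @param model a `metabolic_model` (native or irreversible form).
#' @param medium a `medium_spec` list, see [read_medium_config()]; may be a
#'   plain list with the same fields.
#' @return modified model.
#' @export
apply_medium <- function(model, medium) {
  need <- c(medium$substrate, medium$free, medium$oxygen)
  known <- unique(c(model$rxn_ids, unname(model$original_ids)))
  bad <- setdiff(need, known)
  if (length(bad)) stop("medium names unknown exchange id(s): ",
                        paste(bad, collapse = ", "))
  exch <- exchange_ids(model)
  sub_bound <- medium$substrate_bound %||% 10
  if (sub_bound <= 0) stop("substrate uptake bound must be > 0")

  keep_open <- unique(c(medium$substrate, medium$free, medium$product))
  for (ex in exch) {
    src <- unname(model$original_ids[ex])
    if (src %in% keep_open || ex %in% keep_open) next
    model <- close_uptake(model, ex)
  }
  model <- set_uptake(model, medium$substrate, sub_bound)
  for (ex in medium$free) model <- set_uptake(model, ex, 1000)

  aerobic <- medium$aerobic %||% TRUE
  if (!aerobic) {
    if (length(medium$anaerobic_delete)) {
      model <- knockout(model, medium$anaerobic_delete)
    } else if (!is.null(medium$oxygen)) {
      model <- set_uptake(model, medium$oxygen, 0)
    } else {
      stop("anaerobic medium needs either an oxygen exchange id or reactions to delete")
    }
  } else if (!is.null(medium$oxygen)) {
    model <- set_uptake(model, medium$oxygen, 1000)
  }
  model
}

# split or native columns of an exchange id, with their uptake orientation
uptake_columns <- function(model, id) {
  cols <- expand_directions(model, id)
  met <- vapply(cols, function(cl) {
    nz <- which(model$S[, cl] != 0)
    if (length(nz) != 1L) stop(id, " is not an exchange (single-entry) reaction")
    nz
  }, integer(1))
  sign_in <- vapply(seq_along(cols), function(k) {
    unname(sign(model$S[met[k], cols[k]]))
  }, numeric(1))
  list(cols = cols, produces = sign_in > 0)
}

set_uptake <- function(model, id, bound) {
  uc <- uptake_columns(model, id)
  for (k in seq_along(uc$cols)) {
    cl <- uc$cols[k]
    if (uc$produces[k]) {
      model$upper[cl] <- bound
    } else {
      model$lower[cl] <- -bound
    }
  }
  model
}

close_uptake <- function(model, id) {
  uc <- uptake_columns(model, id)
  for (k in seq_along(uc$cols)) {
    cl <- uc$cols[k]
    if (uc$produces[k]) {
      model$upper[cl] <- min(model$upper[cl], 0)
    } else {
      model$lower[cl] <- max(model$lower[cl], 0)
    }
  }
  model
}

exchange_ids <- function(model) {
  one <- colSums(model$S != 0) == 1L
  model$rxn_ids[one]
}

#' Classify reaction roles
#'
#' Exchanges are detected structurally (single nonzero stoichiometric
#' entry).  Diffusion-based protein-free transports cannot be detected from
#' stoichiometry and come from the configuration, as do the biomass and
#' maintenance reactions; configured roles take precedence over the
#' structural rule (e.g. an ATP-maintenance sink is single-entry but is a
#' maintenance reaction, not an exchange).  Everything else is `internal`.
#'
#' @param model a `metabolic_model`.
#' @param biomass_id biomass reaction id (required).
#' @param maintenance_ids,diffusion_ids configured role lists.
#' @return model with `roles` set.
#' @export
classify_roles <- function(model, biomass_id, maintenance_ids = character(),
                           diffusion_ids = character()) {
  ids <- unique(c(biomass_id, maintenance_ids, diffusion_ids))
  cols <- expand_directions(model, ids)   # validates ids exist
  roles <- rep("internal", n_reactions(model))
  names(roles) <- model$rxn_ids
  roles[exchange_ids(model)] <- "exchange"
  if (length(diffusion_ids))
    roles[expand_directions(model, diffusion_ids)] <- "diffusion_transport"
  if (length(maintenance_ids))
    roles[expand_directions(model, maintenance_ids)] <- "maintenance"
  bio_cols <- expand_directions(model, biomass_id)
  roles[bio_cols] <- "biomass"
  model$roles <- roles
  validate_model(model)
  model
}
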