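# Model input/output: BiGG-style JSON and SBML Level 3 with the FBC
# extension.  Identifiers are preserved verbatim; gene annotations are read
# past and dropped (gene-level mapping is out of scope).

#' Load a constraint-based model
#'
#' @param path file path.
#' @param format `"json"` (BiGG-style) or `"sbml"` (Level 3, FBC v2);
#'   guessed from the file extension by default.
#' @return a `metabolic_model` in its native (possibly reversible) form.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read model file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = read_bigg_json(path), sbml = read_sbml(path))
}

#' Read a BiGG-style JSON model
#' @param path file path.
#' @return a `metabolic_model`.
#' @export
read_bigg_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unreadable JSON model: ",
                                           conditionMessage(e)))
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("model JSON lacks reactions/metabolites")
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids in ", path)
  m <- length(met_ids); n <- length(rxn_ids)
  S <- matrix(0, m, n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n); ub <- numeric(n); obj <- numeric(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    st <- unlist(r$metabolites)
    if (length(st)) {
      i <- match(names(st), met_ids)
      if (anyNA(i)) stop("reaction ", r$id, " references unknown metabolite")
      S[i, j] <- as.numeric(st)
    }
    lb[j] <- r$lower_bound %||% -1000
    ub[j] <- r$upper_bound %||% 1000
    obj[j] <- r$objective_coefficient %||% 0
  }
  metabolic_model(S, lb, ub, obj, met_ids = met_ids, rxn_ids = rxn_ids,
                  id = doc$id %||% basename(path))
}

#' Write a model as BiGG-style JSON
#'
#' Round-trips through [read_bigg_json()]; split-pair bookkeeping is not
#' serialised (re-split after reading).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bigg_json <- function(model, path) {
  mets <- lapply(model$met_ids, function(m) list(id = m))
  rxns <- lapply(seq_along(model$rxn_ids), function(j) {
    sj <- model$S[, j]
    nz <- sj[sj != 0]
    list(id = model$rxn_ids[j],
         metabolites = as.list(nz),
         lower_bound = unname(model$lower[j]),
         upper_bound = unname(model$upper[j]),
         objective_coefficient = unname(model$objective[j]))
  })
  jsonlite::write_json(list(id = model$id, metabolites = mets,
                            reactions = rxns, genes = list()),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SBML Level 3 FBC model
#'
#' Supports the subset of SBML L3 + FBC v2 produced by standard exporters:
#' species, reactions with reactant/product stoichiometries, flux bounds via
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameter references, and the
#' active FBC objective.  Species flagged `boundaryCondition="true"` are
#' dropped from the stoichiometric matrix.
#'
#' @param path file path.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML: ",
                                           conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  met_ids <- sp_id[!boundary]

  par <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                          xml2::xml_attr(par, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("model has no reactions: ", path)
  rxn_ids <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids in ", path)
  n <- length(rxn_ids); m <- length(met_ids)
  S <- matrix(0, m, n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n); ub <- numeric(n)
  for (j in seq_len(n)) {
    node <- rx[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./s:", side, "/s:speciesReference"), ns)
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        if (sid %in% boundary_species(sp_id, boundary)) next
        stoich <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(stoich)) stoich <- 1
        i <- match(sid, met_ids)
        if (is.na(i)) next                       # boundary species
        S[i, j] <- S[i, j] + sgn * stoich
      }
    }
    lbid <- attr_local(node, "lowerFluxBound")
    ubid <- attr_local(node, "upperFluxBound")
    rev <- attr_local(node, "reversible") %in% "true"
    lb[j] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else
      if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else 1000
  }

  obj <- numeric(n)
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    orx <- vapply(fo, attr_local, character(1), name = "reaction")
    oco <- as.numeric(vapply(fo, attr_local, character(1), name = "coefficient"))
    i <- match(orx, rxn_ids)
    obj[i[!is.na(i)]] <- oco[!is.na(i)]
  }
  metabolic_model(S, lb, ub, obj, met_ids = met_ids, rxn_ids = rxn_ids,
                  id = xml2::xml_attr(mdl, "id") %||% basename(path))
}

boundary_species <- function(sp_id, boundary) sp_id[boundary]

# attribute lookup ignoring any namespace prefix (e.g. fbc:lowerFluxBound)
attr_local <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == name)
  if (length(hit) == 0L) NA_character_ else unname(at[[hit[1]]])
}

#' Read a medium / roles configuration file
#'
#' JSON with (all optional unless noted): `substrate` (exchange id,
#' required), `substrate_bound` (uptake, default 10 mmol/gDCW/h), `free`
#' (exchange ids opened to 1000), `aerobic` (logical, default TRUE),
#' `oxygen` (O2 exchange id), `anaerobic_delete` (reaction ids removed for
#' anaerobiosis, e.g. cytochrome c oxidase in yeast), `biomass`,
#' `maintenance`, `diffusion_transport`, `product` ids, and
#' `molecular_weights` (named, g/mol).
#'
#' @param path JSON file path.
#' @return named list (class `medium_spec`).
#' @export
read_medium_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$substrate)) stop("medium config must name a substrate exchange")
  cfg$substrate_bound <- cfg$substrate_bound %||% 10
  if (cfg$substrate_bound <= 0) stop("substrate uptake bound must be > 0")
  cfg$aerobic <- cfg$aerobic %||% TRUE
  cfg$free <- as.character(cfg$free %||% character())
  cfg$diffusion_transport <- as.character(cfg$diffusion_transport %||% character())
  cfg$anaerobic_delete <- as.character(cfg$anaerobic_delete %||% character())
  class(cfg) <- "medium_spec"
  cfg
}
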