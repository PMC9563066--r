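#' Generate a toy metabolic model with prescribed knockout growth ratios
#'
#' Builds a small stoichiometric network whose per-gene single-knockout growth
#' ratios equal `target_ratios` by construction, for testing knockout screens
#' without a genome-scale model. The network is a substrate uptake feeding a
#' linear chain into a hub metabolite consumed by the biomass reaction:
#'
#' * a gene with target ratio 0 (lethal) gates its own serial chain step;
#' * a gene with ratio 1 (neutral) gates one copy of a duplicated chain step
#'   (the other copy carries no rule, so the knockout is bypassed);
#' * a gene with ratio `r` in (0, 1) gates a parallel branch into the hub with
#'   capacity `(1 - r) * uptake`; an unconditional branch carries the
#'   remaining capacity. This requires `sum(1 - r) <= 1` over the partial
#'   genes; otherwise the ratio set is infeasible for this construction.
#'
#' Gene `i` is named `g<i>` in the order of `target_ratios`.
#'
#' @param target_ratios Numeric vector in `[0, 1]`: desired knockout/wild-type
#'   growth ratio per gene.
#' @param uptake Substrate uptake bound (wild-type growth equals this).
#' @return A [metabolic_model()].
#' @examples
#' m <- make_toy_gsmm(c(0.5, 1, 0))
#' fba_growth(m)                         # 10
#' fba_growth(delete_gene(m, "g1"))      # 5
#' @export
make_toy_gsmm <- function(target_ratios, uptake = 10) {
  if (any(target_ratios < 0 | target_ratios > 1))
    stop("target ratios must lie in [0, 1]", call. = FALSE)
  n <- length(target_ratios)
  if (n < 1) stop("need at least one gene", call. = FALSE)
  genes <- paste0("g", seq_len(n))
  partial <- which(target_ratios > 0 & target_ratios < 1)
  lethal <- which(target_ratios == 0)
  neutral <- which(target_ratios == 1)
  open_cap <- uptake * (1 - sum(1 - target_ratios[partial]))
  if (open_cap < -1e-9)
    stop("infeasible ratio set: sum(1 - ratio) over partial genes exceeds 1",
         call. = FALSE)

  # metabolites: chain C0..Cm (one link per lethal gene, one per neutral gene), hub H
  n_links <- length(lethal) + length(neutral)
  mets <- c(paste0("C", 0:n_links), "H")
  rxn <- list()  # each: list(id, stoich = named vector, lb, ub, rule)
  add <- function(id, stoich, ub, rule = NA_character_)
    rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = 0, ub = ub, rule = rule)

  add("EX_up", c(C0 = 1), uptake)
  level <- 0L
  for (g in lethal) {
    st <- stats::setNames(c(-1, 1), c(paste0("C", level), paste0("C", level + 1L)))
    add(paste0("chain_", genes[g]), st, uptake, genes[g])
    level <- level + 1L
  }
  for (g in neutral) {
    st <- stats::setNames(c(-1, 1), c(paste0("C", level), paste0("C", level + 1L)))
    add(paste0("dup_", genes[g], "_gated"), st, uptake, genes[g])
    add(paste0("dup_", genes[g], "_open"), st, uptake)
    level <- level + 1L
  }
  top <- paste0("C", level)
  for (g in partial) {
    st <- stats::setNames(c(-1, 1), c(top, "H"))
    add(paste0("branch_", genes[g]), st, (1 - target_ratios[g]) * uptake, genes[g])
  }
  if (open_cap > 1e-9 || length(partial) == 0L)
    add("branch_open", stats::setNames(c(-1, 1), c(top, "H")), max(open_cap, uptake * (length(partial) == 0L)))
  add("biomass", c(H = -1), uptake * 10)

  S <- matrix(0, length(mets), length(rxn), dimnames = list(mets, vapply(rxn, `[[`, "", "id")))
  for (j in seq_along(rxn)) S[names(rxn[[j]]$stoich), j] <- rxn[[j]]$stoich
  metabolic_model(S,
                  lb = vapply(rxn, `[[`, 0, "lb"),
                  ub = vapply(rxn, `[[`, 0, "ub"),
                  objective = "biomass",
                  reaction_ids = colnames(S), metabolite_ids = mets,
                  genes = genes,
                  rules = vapply(rxn, `[[`, "", "rule"))
}

#' Write / read a toy metabolic model as JSON
#'
#' Plain-text serialisation: the stoichiometric matrix as `(i, j, value)`
#' triplets plus bounds, objective, gene list and rules.
#'
#' @param model A [metabolic_model()].
#' @param path File path.
#' @return `read_toy_gsmm()` returns a [metabolic_model()].
#' @export
write_toy_gsmm <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  nz <- which(model$S != 0, arr.ind = TRUE)
  obj <- list(
    metabolites = model$metabolite_ids,
    reactions = model$reaction_ids,
    S_triplets = data.frame(i = nz[, 1], j = nz[, 2], value = model$S[nz]),
    lb = model$lb, ub = model$ub,
    objective = model$reaction_ids[model$objective],
    genes = model$genes, rules = model$rules
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_toy_gsmm
#' @export
read_toy_gsmm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- matrix(0, length(o$metabolites), length(o$reactions),
              dimnames = list(o$metabolites, o$reactions))
  S[cbind(o$S_triplets$i, o$S_triplets$j)] <- o$S_triplets$value
  rules <- as.character(o$rules)
  rules[rules == "null" | is.na(rules)] <- NA_character_
  metabolic_model(S, lb = o$lb, ub = o$ub, objective = o$objective,
                  reaction_ids = o$reactions, metabolite_ids = o$metabolites,
                  genes = as.character(o$genes), rules = rules)
}

#' Read an SBML Level-3 FBC metabolic model
#'
#' A compact reader for the SBML dialect used by published genome-scale
#' models (Level 3 with the `fbc` package, version 2): species, reactions with
#' stoichiometries, flux bounds referenced through global parameters, the
#' active objective, and `fbc:geneProductAssociation` trees (converted to
#' `and`/`or` rule strings over gene-product labels). Kinetic laws, rule-based
#' maths and units are out of scope.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  ln <- function(...) paste(sprintf("*[local-name()='%s']", c(...)), collapse = "/")

  # SBML-FBC attributes may carry the fbc: namespace prefix
  attr2 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (all(is.na(v))) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }

  params <- xml2::xml_find_all(doc, paste0(".//", ln("listOfParameters", "parameter")))
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, paste0(".//", ln("listOfSpecies", "species")))
  sp_ids <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- sp_ids[!boundary]

  gps <- xml2::xml_find_all(doc, paste0(".//", ln("listOfGeneProducts", "geneProduct")))
  gp_ids <- attr2(gps, "id")
  gp_labels <- attr2(gps, "label")
  gp_label <- stats::setNames(ifelse(is.na(gp_labels), gp_ids, gp_labels), gp_ids)

  assoc_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr2(node, "geneProduct")
      lbl <- gp_label[ref]
      return(if (is.na(lbl)) ref else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_rule, character(1))
    op <- if (nm == "and") " and " else if (nm == "or") " or "
      else return(paste(parts, collapse = " "))
    paste0("(", paste(parts, collapse = op), ")")
  }

  rxns <- xml2::xml_find_all(doc, paste0(".//", ln("listOfReactions", "reaction")))
  rids <- xml2::xml_attr(rxns, "id")
  n <- length(rxns)
  S <- matrix(0, length(mets), n, dimnames = list(mets, rids))
  lb <- numeric(n); ub <- numeric(n); rules <- rep(NA_character_, n)
  bound_of <- function(attr_val, default) {
    if (is.na(attr_val)) return(default)
    v <- pval[attr_val]
    if (is.na(v)) default else unname(v)
  }
  for (j in seq_len(n)) {
    r <- rxns[[j]]
    for (sr in xml2::xml_find_all(r, paste0("./", ln("listOfReactants", "speciesReference")))) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry")); if (is.na(st)) st <- 1
      if (sp %in% mets) S[sp, j] <- S[sp, j] - st
    }
    for (sr in xml2::xml_find_all(r, paste0("./", ln("listOfProducts", "speciesReference")))) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry")); if (is.na(st)) st <- 1
      if (sp %in% mets) S[sp, j] <- S[sp, j] + st
    }
    rev <- xml2::xml_attr(r, "reversible") %in% "true"
    lb[j] <- bound_of(attr2(r, "lowerFluxBound"), if (rev) -1000 else 0)
    ub[j] <- bound_of(attr2(r, "upperFluxBound"), 1000)
    gpa <- xml2::xml_find_first(r, paste0("./", ln("geneProductAssociation")))
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) rules[j] <- assoc_to_rule(kids[[1]])
    }
  }

  obj_ref <- xml2::xml_find_first(doc, paste0(".//", ln("listOfObjectives", "objective", "listOfFluxObjectives", "fluxObjective")))
  if (inherits(obj_ref, "xml_missing"))
    stop("no flux objective found in SBML model", call. = FALSE)
  objective <- attr2(obj_ref, "reaction")

  metabolic_model(S, lb = lb, ub = ub, objective = objective,
                  reaction_ids = rids, metabolite_ids = mets,
                  genes = unname(gp_label), rules = rules)
}
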