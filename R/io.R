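# Model readers/writers.  Three formats:
#  * tsv      — three plain files sharing a prefix: <prefix>.metabolites.tsv
#               (id, compartment, name), <prefix>.reactions.tsv (id,
#               reversible, lower_bound, upper_bound, gene_rule, objective),
#               <prefix>.stoich.tsv (reaction, metabolite, compartment,
#               coefficient — sparse triplets).
#  * bigg_json — the JSON layout used by the BiGG model repository.
#  * sbml     — SBML Level 3 core plus the fbc bounds / gene-association
#               subset, read directly with xml2.

#' Load a metabolic model
#'
#' @param path file path; for `format = "tsv"` the common prefix of the
#'   three component files.
#' @param format one of `"tsv"`, `"bigg_json"`, `"sbml"`.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("tsv", "bigg_json", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tsv = load_model_tsv(path),
         bigg_json = load_model_bigg_json(path),
         sbml = load_model_sbml(path))
}

#' Write a model in the three-file TSV dialect
#'
#' @param model a `metabolic_model`.
#' @param prefix path prefix; writes `<prefix>.metabolites.tsv`,
#'   `<prefix>.reactions.tsv` and `<prefix>.stoich.tsv`.
#' @return the prefix, invisibly.
#' @export
write_model_tsv <- function(model, prefix) {
  stopifnot(inherits(model, "metabolic_model"))
  wt <- function(df, suffix) {
    utils::write.table(df, paste0(prefix, suffix), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(model$metabolites, ".metabolites.tsv")
  rx <- model$reactions
  rx$reversible <- as.integer(rx$reversible)
  rx$objective <- if (is.null(model$objective)) 0 else model$objective
  wt(rx, ".reactions.tsv")
  trip <- Matrix::summary(model$S)
  mk <- met_key(model$metabolites$id, model$metabolites$compartment)
  stoich <- data.frame(reaction = model$reactions$id[trip$j],
                       metabolite = model$metabolites$id[trip$i],
                       compartment = model$metabolites$compartment[trip$i],
                       coefficient = trip$x, stringsAsFactors = FALSE)
  stoich <- stoich[order(match(stoich$reaction, model$reactions$id),
                         match(met_key(stoich$metabolite, stoich$compartment), mk)), ]
  wt(stoich, ".stoich.tsv")
  invisible(prefix)
}

load_model_tsv <- function(prefix) {
  rd <- function(suffix) {
    f <- paste0(prefix, suffix)
    if (!file.exists(f)) stop("missing model component file: ", f)
    utils::read.delim(f, stringsAsFactors = FALSE)
  }
  mets <- rd(".metabolites.tsv")
  mets$name <- as.character(mets$name)
  rxns <- rd(".reactions.tsv")
  rxns$id <- as.character(rxns$id)
  stoich <- rd(".stoich.tsv")
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1])
  if (is.null(rxns$gene_rule)) rxns$gene_rule <- ""
  rxns$gene_rule[is.na(rxns$gene_rule)] <- ""
  unknown <- setdiff(stoich$reaction, rxns$id)
  if (length(unknown))
    stop("stoichiometry references unknown reaction: ",
         paste(unique(unknown), collapse = ", "))
  reactions <- lapply(seq_len(nrow(rxns)), function(j) {
    rows <- stoich[stoich$reaction == rxns$id[j], , drop = FALSE]
    if (nrow(rows) == 0)
      stop("reaction '", rxns$id[j], "' has no stoichiometry entries")
    reaction(id = rxns$id[j],
             participants = data.frame(metabolite = rows$metabolite,
                                       compartment = rows$compartment,
                                       coefficient = rows$coefficient,
                                       stringsAsFactors = FALSE),
             reversible = as.logical(rxns$reversible[j]),
             lower_bound = rxns$lower_bound[j],
             upper_bound = rxns$upper_bound[j],
             gene_rule = rxns$gene_rule[j])
  })
  objective <- NULL
  if (!is.null(rxns$objective) && any(rxns$objective != 0))
    objective <- rxns$objective
  metabolic_model(reactions, metabolites = mets, objective = objective,
                  id = basename(prefix))
}

load_model_bigg_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, compartment = m$compartment,
               name = if (is.null(m$name)) NA_character_ else m$name,
               stringsAsFactors = FALSE)
  }))
  comp_of <- setNames(mets$compartment, mets$id)
  objective <- numeric(length(doc$reactions))
  reactions <- lapply(seq_along(doc$reactions), function(j) {
    r <- doc$reactions[[j]]
    coefs <- unlist(r$metabolites)
    if (!is.null(r$objective_coefficient))
      objective[j] <<- r$objective_coefficient
    lb <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    reaction(id = r$id,
             participants = data.frame(metabolite = names(coefs),
                                       compartment = unname(comp_of[names(coefs)]),
                                       coefficient = unname(coefs),
                                       stringsAsFactors = FALSE),
             reversible = lb < 0,
             lower_bound = lb, upper_bound = ub,
             gene_rule = if (is.null(r$gene_reaction_rule)) "" else
               r$gene_reaction_rule)
  })
  metabolic_model(reactions, metabolites = mets,
                  objective = if (any(objective != 0)) objective else NULL,
                  id = if (is.null(doc$id)) basename(path) else doc$id)
}

load_model_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # work positionally over core + fbc elements

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  mets <- data.frame(id = sp_id,
                     compartment = xml2::xml_attr(sp, "compartment"),
                     name = xml2::xml_attr(sp, "name"),
                     stringsAsFactors = FALSE)
  # parameters referenced by fbc flux bounds
  par <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- setNames(as.numeric(xml2::xml_attr(par, "value")),
                      xml2::xml_attr(par, "id"))
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    side <- function(tag, sign) {
      refs <- xml2::xml_find_all(node, paste0("./", tag, "/speciesReference"))
      if (length(refs) == 0) return(NULL)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      data.frame(species = xml2::xml_attr(refs, "species"),
                 coefficient = sign * st, stringsAsFactors = FALSE)
    }
    part <- rbind(side("listOfReactants", -1), side("listOfProducts", 1))
    if (is.null(part)) stop("reaction '", rid, "' has no participants")
    i <- match(part$species, mets$id)
    if (anyNA(i))
      stop("reaction '", rid, "' references unknown species: ",
           part$species[is.na(i)][1])
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
          else 1000
    gene_rule <- sbml_gene_rule(
      xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']"),
      gp_label)
    reaction(id = rid,
             participants = data.frame(metabolite = part$species,
                                       compartment = mets$compartment[i],
                                       coefficient = part$coefficient,
                                       stringsAsFactors = FALSE),
             reversible = rev, lower_bound = lb, upper_bound = ub,
             gene_rule = gene_rule)
  })

  # active fbc objective, if declared
  objective <- NULL
  fo <- xml2::xml_find_all(
    doc, ".//*[local-name()='objective'][1]//*[local-name()='fluxObjective']")
  if (length(fo)) {
    objective <- setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                          xml2::xml_attr(fo, "reaction"))
    objective[is.na(objective)] <- 1
  }
  mdl_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  metabolic_model(reactions, metabolites = mets, objective = objective,
                  id = if (is.na(mdl_id)) basename(path) else mdl_id)
}

sbml_gene_rule <- function(node, gp_label) {
  if (inherits(node, "xml_missing") || is.null(node) || length(node) == 0)
    return("")
  walk <- function(n) {
    nm <- xml2::xml_name(n)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(n, "geneProduct")
      lbl <- gp_label[ref]
      return(if (is.na(lbl)) ref else unname(lbl))
    }
    kids <- xml2::xml_children(n)
    parts <- vapply(kids, walk, character(1))
    if (nm == "and") return(paste0("(", paste(parts, collapse = " AND "), ")"))
    if (nm == "or") return(paste0("(", paste(parts, collapse = " OR "), ")"))
    if (length(parts) == 1) return(parts)
    stop("unsupported gene association element: ", nm)
  }
  kids <- xml2::xml_children(node)
  if (length(kids) == 0) return("")
  walk(kids[[1]])
}
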