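# Core containers: `reaction` (participants + bounds + gene rule) and
# `metabolic_model` (ordered metabolites/reactions + sparse stoichiometric
# matrix S, metabolites in rows, reactions in columns).

#' Construct a reaction
#'
#' @param id reaction identifier (arbitrary non-empty string; numeric ids
#'   are coerced to character and treated as opaque).
#' @param participants data frame with columns `metabolite`, `compartment`,
#'   `coefficient` (negative = substrate, positive = product).
#' @param reversible logical; reversible reactions admit negative flux.
#' @param lower_bound,upper_bound flux capacity bounds (consistent units
#'   model-wide).  Non-finite bounds are clamped to the conventional
#'   default capacity of 1000 (0 lower for irreversible reactions).
#' @param gene_rule gene association string (see [parse_gene_rule()]);
#'   `""` means no known gene association.
#' @return object of class `reaction`.
#' @export
reaction <- function(id, participants, reversible = FALSE,
                     lower_bound = if (reversible) -1000 else 0,
                     upper_bound = 1000, gene_rule = "") {
  id <- as.character(id)
  stopifnot(length(id) == 1, nzchar(id), is.data.frame(participants))
  req <- c("metabolite", "compartment", "coefficient")
  if (!all(req %in% names(participants)))
    stop("participants needs columns: ", paste(req, collapse = ", "))
  if (nrow(participants) == 0)
    stop("reaction '", id, "' has no participants")
  key <- met_key(participants$metabolite, participants$compartment)
  if (anyDuplicated(key))
    stop("reaction '", id, "' lists participant '",
         key[duplicated(key)][1], "' twice")
  if (!is.finite(lower_bound)) lower_bound <- if (reversible) -1000 else 0
  if (!is.finite(upper_bound)) upper_bound <- 1000
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound exceeds upper_bound")
  if (!reversible && lower_bound < 0)
    stop("reaction '", id, "' is irreversible but lower_bound < 0")
  rownames(participants) <- NULL
  structure(list(id = id,
                 participants = participants[, req],
                 reversible = isTRUE(reversible),
                 lower_bound = lower_bound,
                 upper_bound = upper_bound,
                 gene_rule = if (is.na(gene_rule)) "" else gene_rule),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction>", x$id, "\n ", format_reaction_equation(x), "\n",
      " bounds [", x$lower_bound, ",", x$upper_bound, "]",
      if (nzchar(x$gene_rule)) paste0("  gpr: ", x$gene_rule), "\n")
  invisible(x)
}

# compartment-qualified metabolite key, the identity used model-wide
met_key <- function(metabolite, compartment) {
  paste0(metabolite, "[", compartment, "]")
}

#' Assemble a metabolic model from reactions
#'
#' Builds the ordered metabolite list (first appearance order), the sparse
#' stoichiometric matrix and the gene set, validating the container
#' invariants (unique ids, consistent dimensions, reversibility/bound
#' agreement).
#'
#' @param reactions list of [reaction()] objects.
#' @param metabolites optional data frame (`id`, `compartment`, optional
#'   `name`) fixing metabolite order; metabolites referenced by reactions
#'   but absent from it are an error.
#' @param objective optional numeric vector of objective coefficients, one
#'   per reaction (named or positional).
#' @param id model identifier.
#' @return object of class `metabolic_model` with elements `metabolites`
#'   (data frame), `reactions` (data frame of id/reversible/bounds/
#'   gene_rule), `S` (sparse `dgCMatrix`, metabolites x reactions, dimnames
#'   set to metabolite keys and reaction ids), `genes`, `objective`.
#' @export
metabolic_model <- function(reactions, metabolites = NULL, objective = NULL,
                            id = "model") {
  stopifnot(is.list(reactions), length(reactions) > 0)
  if (!all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("all elements of `reactions` must be reaction objects")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id: ", rxn_ids[duplicated(rxn_ids)][1])

  part <- do.call(rbind, lapply(seq_along(reactions), function(j) {
    p <- reactions[[j]]$participants
    data.frame(j = j, key = met_key(p$metabolite, p$compartment),
               metabolite = p$metabolite, compartment = p$compartment,
               coefficient = p$coefficient, stringsAsFactors = FALSE)
  }))

  if (is.null(metabolites)) {
    first <- !duplicated(part$key)
    metabolites <- data.frame(id = part$metabolite[first],
                              compartment = part$compartment[first],
                              name = NA_character_,
                              stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "compartment") %in% names(metabolites)))
    if (is.null(metabolites$name)) metabolites$name <- NA_character_
    metabolites <- metabolites[, c("id", "compartment", "name")]
  }
  met_keys <- met_key(metabolites$id, metabolites$compartment)
  if (anyDuplicated(met_keys))
    stop("duplicate metabolite id: ", met_keys[duplicated(met_keys)][1])
  miss <- setdiff(part$key, met_keys)
  if (length(miss))
    stop("stoichiometry references unknown metabolite: ",
         paste(miss, collapse = ", "))

  S <- Matrix::sparseMatrix(i = match(part$key, met_keys), j = part$j,
                            x = part$coefficient,
                            dims = c(nrow(metabolites), length(reactions)),
                            dimnames = list(met_keys, rxn_ids))

  rxns <- data.frame(
    id = rxn_ids,
    reversible = vapply(reactions, `[[`, logical(1), "reversible"),
    lower_bound = vapply(reactions, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(reactions, `[[`, numeric(1), "upper_bound"),
    gene_rule = vapply(reactions, `[[`, character(1), "gene_rule"),
    stringsAsFactors = FALSE)
  rownames(rxns) <- NULL

  genes <- sort(unique(unlist(lapply(rxns$gene_rule, genes_in_rule))))

  if (!is.null(objective)) {
    if (!is.null(names(objective))) {
      obj <- setNames(numeric(length(rxn_ids)), rxn_ids)
      unknown <- setdiff(names(objective), rxn_ids)
      if (length(unknown))
        stop("objective references unknown reaction: ",
             paste(unknown, collapse = ", "))
      obj[names(objective)] <- objective
      objective <- unname(obj)
    }
    stopifnot(length(objective) == length(rxn_ids))
  }

  structure(list(id = id, metabolites = metabolites, reactions = rxns,
                 S = S, genes = genes, objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " ", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,",
      length(x$genes), "genes\n",
      " ", sum(x$reactions$reversible), "reversible,",
      length(exchange_reactions(x)), "exchange reactions\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param dense return a base dense matrix instead of the sparse form.
#' @return metabolites x reactions matrix; entry (i, j) is the coefficient
#'   of metabolite i in reaction j (negative = consumed).
#' @export
stoichiometric_matrix <- function(model, dense = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (dense) as.matrix(model$S) else model$S
}

#' Reconstruct a single reaction object from a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @return a `reaction` object.
#' @export
model_reaction <- function(model, id) {
  j <- match(id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", id)
  col <- model$S[, j]
  nz <- which(col != 0)
  keys <- rownames(model$S)[nz]
  i <- match(keys, met_key(model$metabolites$id, model$metabolites$compartment))
  reaction(id = id,
           participants = data.frame(
             metabolite = model$metabolites$id[i],
             compartment = model$metabolites$compartment[i],
             coefficient = as.numeric(col[nz]),
             stringsAsFactors = FALSE),
           reversible = model$reactions$reversible[j],
           lower_bound = model$reactions$lower_bound[j],
           upper_bound = model$reactions$upper_bound[j],
           gene_rule = model$reactions$gene_rule[j])
}

#' Exchange reactions of a model
#'
#' Exchange (boundary) reactions touch a single metabolite, moving mass in
#' or out of the system.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  n_part <- Matrix::colSums(model$S != 0)
  model$reactions$id[n_part == 1]
}
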