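# Synthetic study-condition generator: small stoichiometrically consistent
# models (parallel branches between one imported source and one exported
# sink metabolite) with random gene rules, plus paired normal/disease
# expression replicates in which the genes of planted reactions are
# down-shifted.  Everything is a pure function of the spec (seeded).

#' Specification for a synthetic model and expression pair
#'
#' The generated network is a set of parallel branches (chains of 1:1
#' conversions) from a source metabolite, fed by an import exchange, to a
#' sink metabolite drained by an export; extra exchanges drain random
#' intermediates.  Internal reactions carry a structural capacity of 10
#' flux units; exchanges 1000.  Each internal reaction has its own 1-3
#' gene AND/OR rule.  Baseline gene expression is log-normal (meanlog 3,
#' sdlog 0.5) shared across conditions; replicates add log-scale noise
#' (sdlog 0.1); in disease the planted reactions' genes are shifted down
#' by `effect` baseline standard deviations.
#'
#' @param n_metabolites number of metabolites (>= 3).
#' @param n_internal_reactions number of internal reactions; must be at
#'   least `n_metabolites - 1` so every intermediate sits on a branch.
#' @param n_exchange_reactions number of exchange reactions (>= 2: one
#'   import, one sink export; extras drain random intermediates).
#' @param genes_per_reaction integer range (length 2) of genes per rule.
#' @param n_planted number of reactions to perturb in disease.
#' @param effect perturbation size in baseline standard deviations; 0
#'   gives the null condition (no true differential reaction).
#' @param seed integer RNG seed; generation is deterministic given the
#'   spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 20, n_internal_reactions = 26,
                           n_exchange_reactions = 3,
                           genes_per_reaction = c(1, 3),
                           n_planted = 1, effect = 4, seed = 0) {
  stopifnot(n_metabolites >= 3,
            n_internal_reactions >= n_metabolites - 1,
            n_exchange_reactions >= 2,
            length(genes_per_reaction) == 2,
            genes_per_reaction[1] >= 1,
            genes_per_reaction[2] >= genes_per_reaction[1],
            n_planted >= 0, effect >= 0)
  structure(list(n_metabolites = n_metabolites,
                 n_internal_reactions = n_internal_reactions,
                 n_exchange_reactions = n_exchange_reactions,
                 genes_per_reaction = as.integer(genes_per_reaction),
                 n_planted = n_planted, effect = effect,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic metabolic model
#'
#' @param spec a [synthetic_spec()].
#' @return a `metabolic_model` with attributes `certificate` (a nonzero
#'   flux vector satisfying `S v = 0` within bounds, certifying
#'   feasibility) and `branches` (list of internal reaction ids per
#'   branch).
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_model_impl(spec))
}

generate_model_impl <- function(spec) {
  n_int <- spec$n_internal_reactions
  n_met <- spec$n_metabolites
  n_branch <- n_int - n_met + 2

  # branch lengths: partition n_int reactions over n_branch chains
  lens <- rep(1L, n_branch)
  extra <- n_int - n_branch
  if (extra > 0) {
    add <- table(sample.int(n_branch, extra, replace = TRUE))
    lens[as.integer(names(add))] <- lens[as.integer(names(add))] + as.integer(add)
  }

  inter_ids <- sprintf("m%02d", seq_len(n_met - 2))
  next_inter <- 1L
  rxn_idx <- 1L
  reactions <- list()
  branches <- vector("list", n_branch)
  gene_counter <- 0L

  make_rule <- function() {
    k <- sample(seq(spec$genes_per_reaction[1], spec$genes_per_reaction[2]), 1)
    genes <- sprintf("g%03d", gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    if (k == 1) return(genes)
    op <- sample(c(" AND ", " OR "), 1)
    if (k == 2 || stats::runif(1) < 0.5)
      return(paste(genes, collapse = op))
    paste0("(", paste(genes[1:2], collapse = op), ")",
           if (op == " AND ") " OR " else " AND ", genes[3])
  }

  for (b in seq_len(n_branch)) {
    chain_mets <- c("src",
                    if (lens[b] > 1) inter_ids[next_inter + seq_len(lens[b] - 1) - 1L],
                    "snk")
    next_inter <- next_inter + lens[b] - 1L
    ids <- character(lens[b])
    for (s in seq_len(lens[b])) {
      rev <- stats::runif(1) < 0.3
      id <- sprintf("R%02d", rxn_idx)
      reactions[[rxn_idx]] <- reaction(
        id = id,
        participants = data.frame(
          metabolite = c(chain_mets[s], chain_mets[s + 1]),
          compartment = "c", coefficient = c(-1, 1),
          stringsAsFactors = FALSE),
        reversible = rev,
        lower_bound = if (rev) -10 else 0,
        upper_bound = 10,
        gene_rule = make_rule())
      ids[s] <- id
      rxn_idx <- rxn_idx + 1L
    }
    branches[[b]] <- ids
  }

  ex <- list(reaction("EX_src",
                      data.frame(metabolite = "src", compartment = "c",
                                 coefficient = 1, stringsAsFactors = FALSE),
                      lower_bound = 0, upper_bound = 1000),
             reaction("EX_snk",
                      data.frame(metabolite = "snk", compartment = "c",
                                 coefficient = -1, stringsAsFactors = FALSE),
                      lower_bound = 0, upper_bound = 1000))
  n_extra <- spec$n_exchange_reactions - 2
  if (n_extra > 0) {
    pool <- inter_ids[seq_len(min(length(inter_ids), n_extra))]
    drains <- if (length(inter_ids) > n_extra)
      sample(inter_ids, n_extra) else pool
    ex <- c(ex, lapply(drains, function(m) {
      reaction(paste0("EX_", m),
               data.frame(metabolite = m, compartment = "c",
                          coefficient = -1, stringsAsFactors = FALSE),
               lower_bound = 0, upper_bound = 1000)
    }))
  }

  all_rxns <- c(reactions, ex)
  exports <- vapply(ex[-1], `[[`, character(1), "id")
  objective <- setNames(rep(1, length(exports)), exports)
  mets <- data.frame(id = c("src", inter_ids, "snk"),
                     compartment = "c", name = NA_character_,
                     stringsAsFactors = FALSE)
  model <- metabolic_model(all_rxns, metabolites = mets,
                           objective = objective,
                           id = sprintf("synthetic_seed%d", spec$seed))

  # certificate: one unit through the first branch
  cert <- setNames(numeric(nrow(model$reactions)), model$reactions$id)
  cert[c("EX_src", branches[[1]], "EX_snk")] <- 1
  stopifnot(max(abs(model$S %*% cert)) < 1e-12)
  attr(model, "certificate") <- cert
  attr(model, "branches") <- branches
  model
}

#' Generate paired normal/disease expression profiles
#'
#' Two replicates per condition.  The planted reactions are the bottleneck
#' (lowest baseline expression) reactions of the `n_planted` branches with
#' the highest minimum baseline expression: a knockdown is planted where
#' there is activity to lose, since perturbing an already-silent reaction
#' is invisible to any flux-based method.
#'
#' @param model model from [generate_model()] (its `branches` attribute is
#'   required).
#' @param spec the same [synthetic_spec()].
#' @return list with `normal` and `disease` (each a list of two
#'   [expression_profile()]s) and `planted` (character vector of perturbed
#'   reaction ids).
#' @export
generate_expression_pair <- function(model, spec) {
  stopifnot(inherits(model, "metabolic_model"), inherits(spec, "synthetic_spec"))
  branches <- attr(model, "branches")
  if (is.null(branches)) stop("model lacks the generator's branch metadata")
  stopifnot(spec$n_planted <= spec$n_internal_reactions)
  with_seed((spec$seed + 10007L) %% .Machine$integer.max,
            generate_expression_impl(model, spec, branches))
}

generate_expression_impl <- function(model, spec, branches) {
  genes <- model$genes
  baseline <- setNames(stats::rnorm(length(genes), mean = 3, sd = 0.5), genes)

  base_score <- reaction_expression(model,
                                    expression_profile(exp(baseline), "baseline"))
  branch_min <- vapply(branches, function(ids) min(base_score[ids]), numeric(1))
  ord <- order(-branch_min)
  planted <- character(0)
  if (spec$n_planted > 0) {
    chosen <- ord[seq_len(min(spec$n_planted, length(branches)))]
    planted <- vapply(chosen, function(b) {
      ids <- branches[[b]]
      ids[which.min(base_score[ids])]
    }, character(1))
  }
  planted_genes <- unique(unlist(lapply(planted, function(r) {
    genes_in_rule(model$reactions$gene_rule[model$reactions$id == r])
  })))

  shift <- setNames(numeric(length(genes)), genes)
  shift[planted_genes] <- -spec$effect * 0.5   # effect in baseline SD units

  replicate_profile <- function(condition, rep_i, shifted) {
    noise <- stats::rnorm(length(genes), mean = 0, sd = 0.1)
    lvl <- exp(baseline + (if (shifted) shift else 0) + noise)
    expression_profile(setNames(lvl, genes),
                       sprintf("%s/rep%d", condition, rep_i))
  }
  list(normal = list(replicate_profile("normal", 1, FALSE),
                     replicate_profile("normal", 2, FALSE)),
       disease = list(replicate_profile("disease", 1, TRUE),
                      replicate_profile("disease", 2, TRUE)),
       planted = planted)
}
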