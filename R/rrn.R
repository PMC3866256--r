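# Reaction-reaction network: nodes are reactions, an undirected edge links
# two reactions sharing at least one (compartment-qualified) metabolite.
# The working subnetwork is the largest k-means cluster of the reactions'
# metabolite-incidence features.

#' Currency metabolites commonly excluded from reaction graphs
#'
#' Ubiquitous cofactors whose sharing links most of the network; excluding
#' them is standard reaction-graph practice but is OFF by default here
#' because several of them (e.g. `pi`, `nadh`) can themselves be biomarker
#' candidates.
#'
#' @param compartments compartment letters to qualify the ids with.
#' @return character vector of compartment-qualified metabolite ids.
#' @export
currency_metabolites <- function(compartments = c("c", "m", "x", "e")) {
  base <- c("h2o", "h", "atp", "adp", "pi", "nadh", "nad", "nadph", "nadp",
            "coa", "co2")
  as.vector(outer(base, compartments, met_key))
}

#' Build the reaction-reaction graph
#'
#' @param model a `metabolic_model`.
#' @param exclude compartment-qualified metabolite ids to ignore when
#'   linking (e.g. [currency_metabolites()]).
#' @return an undirected [igraph::igraph] with one node per reaction and an
#'   edge between reactions sharing a non-excluded metabolite; the edge
#'   attribute `shared` lists the shared metabolites (comma-separated).
#' @export
build_reaction_graph <- function(model, exclude = character()) {
  stopifnot(inherits(model, "metabolic_model"))
  inc <- stoichiometric_matrix(model) != 0        # metabolites x reactions
  keep <- !(rownames(inc) %in% exclude)
  inc <- inc[keep, , drop = FALSE]
  # reactions sharing >= 1 metabolite: gram matrix of the incidence pattern
  shared_counts <- Matrix::t(inc) %*% inc
  adj <- as.matrix(shared_counts) > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- model$reactions$id
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    mets <- rownames(inc)
    shared <- vapply(seq_len(nrow(ends)), function(e) {
      a <- match(ends[e, 1], model$reactions$id)
      b <- match(ends[e, 2], model$reactions$id)
      paste(mets[inc[, a] & inc[, b]], collapse = ",")
    }, character(1))
    igraph::E(g)$shared <- shared
  }
  g
}

#' Reaction feature matrix for clustering
#'
#' One row per reaction.  The default binary encoding marks which
#' metabolites participate; `signed = TRUE` uses the raw stoichiometric
#' coefficients instead.
#'
#' @param model a `metabolic_model`.
#' @param signed use signed stoichiometric coefficients.
#' @return numeric matrix, reactions x metabolites, dimnames set.
#' @export
reaction_features <- function(model, signed = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- as.matrix(stoichiometric_matrix(model))
  m <- if (signed) t(S) else t(S != 0) * 1
  dimnames(m) <- list(model$reactions$id, rownames(S))
  m
}

#' k-means clustering of reactions
#'
#' Partitions the feature rows into `k` clusters by [stats::kmeans()]
#' (Euclidean distance, `nstart` restarts keeping the best inertia),
#' deterministic given `seed`.  If `k` exceeds the number of distinct
#' rows, `k` is reduced to that count and the reduction is recorded.
#'
#' @param features matrix from [reaction_features()].
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart random restarts.
#' @return object of class `cluster_assignment`: named integer vector of
#'   cluster indices in `0..k-1`, with attributes `k`, `seed`,
#'   `k_reduced`, `sizes`.
#' @export
kmeans_cluster <- function(features, k = 50, seed = 0, nstart = 10) {
  stopifnot(is.matrix(features), nrow(features) >= 1, k >= 1)
  n_distinct <- nrow(unique(features))
  k_eff <- as.integer(min(k, n_distinct))
  assign <- if (k_eff == 1) {
    rep(1L, nrow(features))
  } else if (k_eff == n_distinct) {
    # one cluster per distinct row (inertia 0); stats::kmeans needs k < n
    keys <- apply(features, 1, paste, collapse = "\r")
    match(keys, unique(keys))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::kmeans(features, centers = k_eff, nstart = nstart,
                  iter.max = 100)$cluster
  }
  out <- setNames(as.integer(assign) - 1L, rownames(features))
  structure(out, class = "cluster_assignment", k = k_eff, seed = seed,
            k_reduced = k_eff < k,
            sizes = tabulate(assign, nbins = k_eff))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("<cluster_assignment>", length(x), "items in", attr(x, "k"),
      "clusters (seed", attr(x, "seed"), ")",
      if (attr(x, "k_reduced")) "[k reduced to distinct rows]", "\n",
      " sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Induced subgraph of the largest cluster
#'
#' @param graph reaction graph from [build_reaction_graph()].
#' @param assignment a `cluster_assignment` covering the graph's nodes.
#' @return induced [igraph::igraph] on the most populous cluster; ties are
#'   broken toward the lowest cluster index and flagged in the graph
#'   attributes `cluster` and `size_tie`.
#' @export
largest_cluster_subgraph <- function(graph, assignment) {
  stopifnot(igraph::is_igraph(graph), inherits(assignment, "cluster_assignment"))
  nodes <- igraph::V(graph)$name
  miss <- setdiff(nodes, names(assignment))
  if (length(miss))
    stop("assignment does not cover graph nodes: ",
         paste(miss, collapse = ", "))
  cl <- assignment[nodes]
  sizes <- table(cl)
  best_size <- max(sizes)
  winners <- as.integer(names(sizes)[sizes == best_size])
  win <- min(winners)
  sub <- igraph::induced_subgraph(graph, nodes[cl == win])
  sub <- igraph::set_graph_attr(sub, "cluster", win)
  igraph::set_graph_attr(sub, "size_tie", length(winners) > 1)
}

#' Export a reaction graph for Cytoscape
#'
#' `sif` writes `a shares_metabolite b` lines (isolated nodes as bare node
#' lines, per SIF convention); `graphml` writes GraphML with the `shared`
#' edge attribute preserved.
#'
#' @param graph an igraph reaction graph.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("sif", "graphml")) {
  stopifnot(igraph::is_igraph(graph), igraph::vcount(graph) > 0)
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("cannot write graph: no such directory: ", dirname(path))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ends <- if (igraph::ecount(graph) > 0)
      igraph::ends(graph, igraph::E(graph)) else
      matrix(character(), ncol = 2)
    lines <- if (nrow(ends)) paste(ends[, 1], "shares_metabolite", ends[, 2])
             else character()
    isolated <- setdiff(igraph::V(graph)$name, as.vector(ends))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Read a GraphML reaction graph
#'
#' @param path GraphML file written by [export_graph()].
#' @return an igraph object.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}
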