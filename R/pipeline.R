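# Run configuration and the two end-to-end pipelines.  All tunables are
# collected (and validated) up front in a single config object; every
# written report embeds it, and re-running with the same config and inputs
# reproduces byte-identical outputs.

#' Pipeline run configuration
#'
#' Collects and validates every tunable of the FPC and RRN pipelines.
#'
#' @param q_low,q_high activity-class thresholds ([classify_activity()]).
#' @param tighten capacity-scaling floor ([build_condition_lp()]).
#' @param fix_objective FVA objective fraction ([flux_interval()]); `NA`
#'   disables objective fixing.
#' @param theta_overlap,theta_shift significance thresholds
#'   ([compare_intervals()]).
#' @param k number of k-means clusters ([kmeans_cluster()]).
#' @param seed RNG seed funnelling all randomness.
#' @param d PageRank residual probability ([pagerank()]).
#' @param tol PageRank convergence tolerance.
#' @param top_n reactions retained by [select_significant()].
#' @param exclude_currency drop [currency_metabolites()] when building the
#'   reaction graph.
#' @param normalized_pagerank use the conventional normalized PageRank.
#' @return object of class `fluxmark_config` (a validated named list).
#' @export
fluxmark_config <- function(q_low = 0.25, q_high = 0.75, tighten = 0.1,
                            fix_objective = 0.9, theta_overlap = 0.2,
                            theta_shift = 1.0, k = 50, seed = 0, d = 0.85,
                            tol = 1e-10, top_n = 5,
                            exclude_currency = FALSE,
                            normalized_pagerank = FALSE) {
  cfg <- list(q_low = q_low, q_high = q_high, tighten = tighten,
              fix_objective = fix_objective, theta_overlap = theta_overlap,
              theta_shift = theta_shift, k = as.integer(k),
              seed = as.integer(seed), d = d, tol = tol,
              top_n = as.integer(top_n),
              exclude_currency = isTRUE(exclude_currency),
              normalized_pagerank = isTRUE(normalized_pagerank))
  validate_config(cfg)
  structure(cfg, class = "fluxmark_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(q_low >= 0 && q_high <= 1 && q_low < q_high))
      stop("config: need 0 <= q_low < q_high <= 1")
    if (!(tighten > 0 && tighten <= 1))
      stop("config: tighten must be in (0, 1]")
    if (!is.na(fix_objective) && !(fix_objective > 0 && fix_objective <= 1))
      stop("config: fix_objective must be in (0, 1] or NA")
    if (!(theta_overlap >= 0 && theta_overlap <= 1))
      stop("config: theta_overlap must be in [0, 1]")
    if (theta_shift < 0) stop("config: theta_shift must be >= 0")
    if (k < 1) stop("config: k must be >= 1")
    if (!(d > 0 && d < 1)) stop("config: d must be in (0, 1)")
    if (tol <= 0) stop("config: tol must be positive")
    if (top_n < 1) stop("config: top_n must be >= 1")
  })
  invisible(cfg)
}

#' Read a configuration file
#'
#' Accepts either a flat `key = value` file (comments starting with `#`
#' ignored) or a JSON report written by [run_fpc()]/[run_rrn()], whose
#' embedded `config` manifest is extracted — so any emitted report can
#' reproduce its own run.  Keys absent from the file keep their defaults.
#'
#' @param path file path.
#' @return a `fluxmark_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- trimws(readLines(path))
  if (length(lines) && startsWith(lines[1], "{")) {
    doc <- jsonlite::read_json(path)
    if (is.null(doc$config)) stop("JSON file has no config manifest: ", path)
    cfg <- doc$config
    cfg$fix_objective <- if (is.null(cfg$fix_objective)) NA_real_ else
      cfg$fix_objective
    return(do.call(fluxmark_config, cfg))
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    defaults <- formals(fluxmark_config)
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    args[[key]] <- if (val %in% c("true", "TRUE", "false", "FALSE"))
      as.logical(toupper(val)) else as.numeric(val)
  }
  do.call(fluxmark_config, args)
}

#' @export
print.fluxmark_config <- function(x, ...) {
  cat("<fluxmark_config>\n")
  for (k in names(x)) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

as_profile_list <- function(x) {
  if (inherits(x, "expression_profile")) list(x)
  else { stopifnot(is.list(x)); x }
}

#' Run the flux profile comparison pipeline
#'
#' Executes the five FPC stages for each normal/disease expression pair:
#' (1) expression mapped onto reactions, (2) activity-tightened condition
#' LP models, (3) flux intervals by FVA under each condition, (4)
#' interval-divergence significance, (5) consensus across pairs and
#' gene/metabolite biomarker extraction.
#'
#' @param model a `metabolic_model`.
#' @param normal,disease [expression_profile()]s (or lists of them; pair
#'   `i` compares `normal[[i]]` against `disease[[i]]`).
#' @param config a [fluxmark_config()].
#' @param out_dir if given, writes per-pair divergence TSVs, the report
#'   and a reproducibility manifest there.
#' @return object of class `fpc_result`: list with `report`
#'   ([extract_biomarkers()] output), `consensus`, `divergences`,
#'   `intervals`, `config`.
#' @export
run_fpc <- function(model, normal, disease, config = fluxmark_config(),
                    out_dir = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(config, "fluxmark_config"))
  normal <- as_profile_list(normal)
  disease <- as_profile_list(disease)
  if (length(normal) == 0 || length(disease) == 0)
    stop("need at least one normal and one disease expression profile")
  if (length(normal) != length(disease))
    stop("normal and disease profile lists must pair up 1:1 (got ",
         length(normal), " vs ", length(disease), ")")
  fix <- if (is.na(config$fix_objective)) NULL else config$fix_objective

  condition_intervals <- function(profile) {
    scores <- reaction_expression(model, profile)
    state <- classify_activity(scores, q_low = config$q_low,
                               q_high = config$q_high,
                               condition = profile$condition)
    cm <- build_condition_lp(model, state, tighten = config$tighten)
    flux_interval(cm, fix_objective = fix)
  }

  divergences <- vector("list", length(normal))
  intervals <- vector("list", length(normal))
  for (i in seq_along(normal)) {
    iv_n <- condition_intervals(normal[[i]])
    iv_d <- condition_intervals(disease[[i]])
    divergences[[i]] <- compare_intervals(iv_n, iv_d,
                                          theta_overlap = config$theta_overlap,
                                          theta_shift = config$theta_shift)
    intervals[[i]] <- list(normal = iv_n, disease = iv_d)
  }
  consensus <- consensus_over_pairs(divergences)
  report <- extract_biomarkers(model, consensus)

  res <- structure(list(report = report, consensus = consensus,
                        divergences = divergences, intervals = intervals,
                        config = config),
                   class = "fpc_result")
  if (!is.null(out_dir)) write_fpc_result(res, out_dir)
  res
}

#' @export
print.fpc_result <- function(x, ...) {
  cat("<fpc_result>", length(x$divergences), "expression pair(s);",
      length(x$consensus), "consensus significant reaction(s)\n")
  print(x$report)
  invisible(x)
}

write_fpc_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(res$divergences)) {
    utils::write.table(as.data.frame(res$divergences[[i]]),
                       file.path(out_dir, sprintf("divergence_pair%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_report_files(res$report, res$config, out_dir, prefix = "fpc")
  invisible(out_dir)
}

write_report_files <- function(report, config, out_dir, prefix) {
  jsonlite::write_json(
    list(reactions = report$reactions, genes = report$genes,
         metabolites = report$metabolites,
         config = unclass(config)),
    file.path(out_dir, paste0(prefix, "_report.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$genes,
                     file.path(out_dir, paste0(prefix, "_genes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$metabolites,
                     file.path(out_dir, paste0(prefix, "_metabolites.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the reaction-reaction network pipeline
#'
#' Builds the shared-metabolite reaction graph, extracts the largest
#' k-means cluster as the working subnetwork, ranks its reactions with
#' the unnormalized PageRank recursion, scores each reaction by
#' `z = pagerank x |flux|` using an expression-constrained FBA flux
#' profile, and reports the top-scoring reactions with their genes and
#' metabolites.
#'
#' @param model a `metabolic_model`.
#' @param profile the [expression_profile()] used to constrain the flux
#'   state (typically the disease condition), or `NULL` for an
#'   unconstrained FBA profile.
#' @param config a [fluxmark_config()].
#' @param out_dir if given, writes the ranked table, GraphML export,
#'   cluster report and biomarker report there.
#' @return object of class `rrn_result`: list with `graph`, `assignment`,
#'   `subgraph`, `ranks`, `scores`, `selected`, `report`, `flux`,
#'   `config`.
#' @export
run_rrn <- function(model, profile = NULL, config = fluxmark_config(),
                    out_dir = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(config, "fluxmark_config"))
  cm <- model
  if (!is.null(profile)) {
    scores <- reaction_expression(model, profile)
    state <- classify_activity(scores, q_low = config$q_low,
                               q_high = config$q_high,
                               condition = profile$condition)
    cm <- build_condition_lp(model, state, tighten = config$tighten)
  }
  flux <- solve_fba(cm)

  exclude <- if (config$exclude_currency) currency_metabolites() else character()
  graph <- build_reaction_graph(model, exclude = exclude)
  feats <- reaction_features(model)
  assignment <- kmeans_cluster(feats, k = config$k, seed = config$seed)
  subgraph <- largest_cluster_subgraph(graph, assignment)

  ranks <- pagerank(subgraph, d = config$d, tol = config$tol,
                    normalized = config$normalized_pagerank)
  scores <- combined_score(ranks, flux, restrict = igraph::V(subgraph)$name)
  selected <- select_significant(scores,
                                 top_n = min(config$top_n, length(scores)))
  report <- extract_biomarkers(model, selected$reaction)

  res <- structure(list(graph = graph, assignment = assignment,
                        subgraph = subgraph, ranks = ranks, scores = scores,
                        selected = selected, report = report, flux = flux,
                        config = config),
                   class = "rrn_result")
  if (!is.null(out_dir)) write_rrn_result(res, out_dir)
  res
}

#' @export
print.rrn_result <- function(x, ...) {
  cat("<rrn_result> graph:", igraph::vcount(x$graph), "reactions /",
      igraph::ecount(x$graph), "edges; largest cluster:",
      igraph::vcount(x$subgraph), "reactions (cluster",
      igraph::graph_attr(x$subgraph, "cluster"), ")\n")
  comp <- attr(x$scores, "components")
  top <- comp[order(-comp$z, comp$reaction), ]
  print.data.frame(utils::head(top, nrow(x$selected)), row.names = FALSE)
  invisible(x)
}

write_rrn_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_graph(res$subgraph, file.path(out_dir, "subnetwork.graphml"),
               format = "graphml")
  export_graph(res$subgraph, file.path(out_dir, "subnetwork.sif"),
               format = "sif")
  comp <- attr(res$scores, "components")
  ranked <- comp[order(-comp$z, comp$reaction), ]
  ranked$rank <- seq_len(nrow(ranked))
  utils::write.table(ranked, file.path(out_dir, "ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clusters <- data.frame(reaction = names(res$assignment),
                         cluster = as.integer(res$assignment),
                         stringsAsFactors = FALSE)
  utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report_files(res$report, res$config, out_dir, prefix = "rrn")
  invisible(out_dir)
}
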