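# Node ranking by the unnormalized PageRank recursion
#   P_i = (1 - d) + d * sum_{j in M(i)} P_j / L(j)
# with residual probability d (default 0.85).  Note the teleport term is
# (1 - d), not (1 - d)/N, so ranks sum to about N rather than 1; the
# conventional normalized variant is available behind a flag.  Each
# reaction's final significance score is z_k = p_k * |v_k|, the rank times
# the flux magnitude.

#' Link matrix of a reaction graph
#'
#' Entry `(i, j)` is `1/L(j)` if node `j` links to node `i` and 0
#' otherwise, where `L(j)` is the out-degree of `j`; every undirected edge
#' contributes a link in both directions, so each non-dangling column sums
#' to 1.  Isolated nodes give all-zero (dangling) columns.
#'
#' @param graph an undirected igraph graph.
#' @return object of class `link_matrix`: list with `L` (sparse N x N
#'   matrix, dimnames = node names) and `dangling` (logical per column).
#' @export
link_matrix <- function(graph) {
  stopifnot(igraph::is_igraph(graph), igraph::vcount(graph) > 0)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  A <- (A != 0) * 1                      # simple graph: multiplicity ignored
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  scale <- ifelse(dangling, 0, 1 / pmax(deg, 1))
  L <- A %*% Matrix::Diagonal(x = scale)
  dimnames(L) <- dimnames(A)
  structure(list(L = L, dangling = dangling), class = "link_matrix")
}

#' PageRank of a reaction graph
#'
#' Iterates `r <- (1 - d) * 1 + d * L r` from the all-ones vector until
#' the infinity-norm change falls below `tol`.  This is the unnormalized
#' fixed point: isolated (dangling) nodes contribute nothing and settle at
#' `1 - d`, and for a connected undirected graph the ranks sum to about
#' the node count.  With `normalized = TRUE` the teleport term is
#' `(1 - d)/N` and dangling mass is redistributed uniformly, giving the
#' conventional probability-vector PageRank.
#'
#' @param x a `link_matrix`, or an igraph graph (converted internally).
#' @param d residual (damping) probability in (0, 1).
#' @param tol convergence tolerance on the infinity norm.
#' @param max_iter iteration cap.
#' @param normalized use the conventional normalized variant.
#' @return object of class `rank_vector`: named numeric vector of ranks
#'   with attributes `d`, `iterations`, `residual`, `normalized`.
#' @export
pagerank <- function(x, d = 0.85, tol = 1e-10, max_iter = 10000,
                     normalized = FALSE) {
  if (igraph::is_igraph(x)) x <- link_matrix(x)
  stopifnot(inherits(x, "link_matrix"), d > 0, d < 1)
  L <- x$L
  n <- ncol(L)
  teleport <- if (normalized) (1 - d) / n else (1 - d)
  r <- rep(if (normalized) 1 / n else 1, n)
  for (it in seq_len(max_iter)) {
    lr <- as.numeric(L %*% r)
    if (normalized && any(x$dangling))
      lr <- lr + sum(r[x$dangling]) / n
    r_new <- teleport + d * lr
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      return(structure(setNames(r, colnames(L)), class = "rank_vector",
                       d = d, iterations = it, residual = delta,
                       normalized = normalized))
    }
  }
  stop("PageRank did not converge in ", max_iter,
       " iterations (residual ", format(delta), ")")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat("<rank_vector>", length(x), "nodes, d =", attr(x, "d"),
      if (attr(x, "normalized")) "(normalized)",
      "- converged in", attr(x, "iterations"), "iterations\n")
  print(utils::head(sort(unclass(x), decreasing = TRUE), 8))
  invisible(x)
}

#' Combined rank-times-flux significance score
#'
#' `z_k = p_k * |v_k|`: the PageRank of reaction `k` times the magnitude
#' of its flux (magnitude, because reversible reactions carry signed flux
#' but significance is direction-free).
#'
#' @param p a `rank_vector` (or named numeric ranks).
#' @param v a `flux_profile` (or named numeric flux vector).
#' @param restrict reaction ids to score (default: all ranked nodes).
#' @return object of class `score_vector`: named numeric scores with
#'   attribute `components` (data frame reaction/pagerank/flux/z).
#' @export
combined_score <- function(p, v, restrict = NULL) {
  pv <- if (inherits(p, "rank_vector")) unclass(p) else p
  vv <- if (inherits(v, "flux_profile")) v$v else v
  stopifnot(!is.null(names(pv)), !is.null(names(vv)))
  if (is.null(restrict)) restrict <- names(pv)
  miss_p <- setdiff(restrict, names(pv))
  if (length(miss_p))
    stop("reactions missing a rank value: ", paste(miss_p, collapse = ", "))
  miss <- setdiff(restrict, names(vv))
  if (length(miss))
    stop("reactions missing a flux value: ", paste(miss, collapse = ", "))
  z <- pv[restrict] * abs(vv[restrict])
  structure(z, class = "score_vector",
            components = data.frame(reaction = restrict,
                                    pagerank = unname(pv[restrict]),
                                    flux = unname(vv[restrict]),
                                    z = unname(z),
                                    stringsAsFactors = FALSE))
}

#' Select top-scoring reactions
#'
#' Sorts reactions by score descending (ties broken lexicographically by
#' reaction id) and truncates either to the `top_n` best or to those with
#' score at least `min_score`.  Exactly one criterion must be supplied.
#'
#' @param z a `score_vector` (or named numeric scores).
#' @param top_n number of reactions to keep.
#' @param min_score score cutoff.
#' @return data frame with columns `reaction`, `z`, `rank`; attribute
#'   `ties` flags whether any retained rank was decided by the tie-break.
#' @export
select_significant <- function(z, top_n = NULL, min_score = NULL) {
  if (is.null(top_n) == is.null(min_score))
    stop("supply exactly one of top_n or min_score")
  zz <- unclass(z)
  stopifnot(!is.null(names(zz)))
  ord <- order(-zz, names(zz))
  sorted <- zz[ord]
  keep <- if (!is.null(top_n)) {
    if (top_n <= 0) stop("top_n must be positive")
    seq_len(min(top_n, length(sorted)))
  } else {
    which(sorted >= min_score)
  }
  sel <- sorted[keep]
  tie <- FALSE
  if (length(sel)) {
    tie <- anyDuplicated(sel) > 0
    if (!tie && length(sel) < length(sorted))
      tie <- sorted[length(sel) + 1] == sel[length(sel)]
  }
  out <- data.frame(reaction = names(sel), z = unname(sel),
                    rank = seq_along(sel), stringsAsFactors = FALSE)
  structure(out, ties = tie)
}
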