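# Shared fixtures and independent oracles, all built in code.

# Linear chain EX_in -> A -> B -> C -> EX_out with import capacity `cap`.
chain_model <- function(cap = 5) {
  part <- function(mets, coefs) {
    data.frame(metabolite = mets, compartment = "c", coefficient = coefs,
               stringsAsFactors = FALSE)
  }
  metabolic_model(list(
    reaction("EX_in", part("A", 1), lower_bound = 0, upper_bound = cap),
    reaction("R_AB", part(c("A", "B"), c(-1, 1)), gene_rule = "g1"),
    reaction("R_BC", part(c("B", "C"), c(-1, 1)), gene_rule = "g2 OR g3"),
    reaction("EX_out", part("C", -1), lower_bound = 0, upper_bound = 1000)
  ), objective = c(EX_out = 1), id = "chain")
}

# The five headline reaction equations with their gene associations,
# shipped as a plain-text fixture in inst/extdata.
significant_reaction_table <- function() {
  path <- system.file("extdata", "rrn_significant_reactions.tsv",
                      package = "fluxmark")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(index = "character"))
}

# Independent LP oracle: pracma::linprog on the inequality formulation
# (bounds as A x <= b rows), shifted to x >= 0.
oracle_fba <- function(model, objective) {
  n <- nrow(model$reactions)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  S <- as.matrix(stoichiometric_matrix(model))
  res <- pracma::linprog(cc = -objective, A = diag(n), b = ub - lb,
                         Aeq = S, beq = as.numeric(-S %*% lb),
                         maxiter = 2000, bigM = 1e5)
  list(value = sum(objective * (res$x + lb)), x = res$x + lb)
}

# Vertex-enumeration FVA oracle: enumerates candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing every subset of n - rank(S) variables
# at a bound and solving the remaining square system.
oracle_fva <- function(model, extra_A = NULL, extra_b = NULL) {
  S <- as.matrix(stoichiometric_matrix(model))
  if (!is.null(extra_A)) {
    # encode extra inequality rows a'v >= b via slack: a'v - s = b, 0<=s<=BIG
    S <- rbind(cbind(S, matrix(0, nrow(S), nrow(extra_A))),
               cbind(extra_A, -diag(nrow(extra_A))))
    lb <- c(model$reactions$lower_bound, rep(0, nrow(extra_A)))
    ub <- c(model$reactions$upper_bound, rep(1e6, nrow(extra_A)))
    rhs <- c(rep(0, nrow(S) - nrow(extra_A)), extra_b)
  } else {
    lb <- model$reactions$lower_bound
    ub <- model$reactions$upper_bound
    rhs <- rep(0, nrow(S))
  }
  n <- ncol(S)
  r <- qr(S)$rank
  n_fix <- n - r
  stopifnot(n_fix >= 0)
  verts <- list()
  for (fix_idx in utils::combn(n, n_fix, simplify = FALSE)) {
    free_idx <- setdiff(seq_len(n), fix_idx)
    for (side in 0:(2^n_fix - 1)) {
      at_ub <- as.logical(bitwAnd(side, 2^(seq_len(n_fix) - 1)))
      v_fix <- ifelse(at_ub, ub[fix_idx], lb[fix_idx])
      A <- S[, free_idx, drop = FALSE]
      if (qr(A)$rank < length(free_idx)) next
      b <- rhs - if (n_fix > 0) S[, fix_idx, drop = FALSE] %*% v_fix else 0
      v_free <- qr.solve(A, b)
      v <- numeric(n)
      v[fix_idx] <- v_fix
      v[free_idx] <- v_free
      if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9) &&
          max(abs(S %*% v - rhs)) < 1e-8)
        verts[[length(verts) + 1]] <- v
    }
  }
  stopifnot(length(verts) > 0)
  V <- do.call(rbind, verts)[, seq_len(nrow(model$reactions)), drop = FALSE]
  data.frame(reaction = model$reactions$id,
             v_min = apply(V, 2, min), v_max = apply(V, 2, max),
             stringsAsFactors = FALSE)
}

# Random reaction-equation string in the bracketed dialect plus the parsed
# structure it encodes, for round-trip property tests.
random_equation <- function() {
  n_sub <- sample(1:3, 1)
  n_prod <- sample(1:3, 1)
  mets <- paste0("met", sample(100:999, n_sub + n_prod))
  comp <- sample(letters[1:5], 1)
  coefs <- sample(c(1, 1, 1, 2, 3), n_sub + n_prod, replace = TRUE)
  term <- function(i) {
    q <- if (coefs[i] == 1) "" else paste0("(", coefs[i], ") ")
    paste0(q, mets[i])
  }
  rev <- runif(1) < 0.5
  arrow <- if (rev) " <=> " else " -> "
  list(text = paste0("[", comp, "]:",
                     paste(vapply(seq_len(n_sub), term, ""), collapse = "+"),
                     arrow,
                     paste(vapply(n_sub + seq_len(n_prod), term, ""),
                           collapse = "+")),
       mets = mets, comp = comp, coefs = c(-coefs[seq_len(n_sub)],
                                           coefs[n_sub + seq_len(n_prod)]),
       reversible = rev)
}

# Brute-force O(n^2) edge oracle: pairwise participant-set intersection.
oracle_edges <- function(model, exclude = character()) {
  S <- as.matrix(stoichiometric_matrix(model))
  parts <- lapply(seq_len(ncol(S)), function(j) {
    setdiff(rownames(S)[S[, j] != 0], exclude)
  })
  ids <- model$reactions$id
  out <- character()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a < b && length(intersect(parts[[a]], parts[[b]])) > 0)
        out <- c(out, paste(sort(c(ids[a], ids[b])), collapse = "|"))
    }
  }
  out
}

graph_edge_keys <- function(g) {
  e <- igraph::ends(g, igraph::E(g))
  apply(e, 1, function(x) paste(sort(x), collapse = "|"))
}

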