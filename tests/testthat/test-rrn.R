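test_that("reactions are linked exactly when they share a metabolite", {
  r1 <- parse_reaction_equation("[c]:A -> B", id = "r1")
  r2 <- parse_reaction_equation("[c]:B -> C", id = "r2")
  m <- metabolic_model(list(r1, r2))
  g <- build_reaction_graph(m)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$shared, "B[c]")
  # excluding the shared metabolite removes the edge
  g2 <- build_reaction_graph(m, exclude = "B[c]")
  expect_equal(igraph::ecount(g2), 0)
})

test_that("metabolite identity for edges is compartment-qualified", {
  tab <- significant_reaction_table()
  rxns <- lapply(seq_len(nrow(tab)), function(i)
    parse_reaction_equation(tab$equation[i], id = tab$index[i]))
  m <- metabolic_model(rxns)
  g <- build_reaction_graph(m)
  # the cytosolic phosphate/uridine reaction shares nothing with the
  # peroxisomal hydration reaction
  expect_false(igraph::are_adjacent(g, "3161", "3115"))
})

test_that("edge sets equal the brute-force oracle on synthetic models", {
  for (seed in 1:6) {
    sp <- synthetic_spec(n_metabolites = 12, n_internal_reactions = 18,
                         n_exchange_reactions = 4, seed = seed)
    m <- generate_model(sp)
    g <- build_reaction_graph(m)
    expect_setequal(graph_edge_keys(g), oracle_edges(m))
    # annotations are nonempty on every edge
    expect_true(all(nzchar(igraph::E(g)$shared)))
    expect_equal(sum(igraph::which_loop(g)), 0)
  }
})

test_that("feature rows mirror stoichiometric columns", {
  m <- generate_model(synthetic_spec(seed = 2))
  f <- reaction_features(m)
  S <- as.matrix(stoichiometric_matrix(m))
  expect_equal(unname(f), unname(t(S != 0) * 1))
  fs <- reaction_features(m, signed = TRUE)
  expect_equal(unname(fs), unname(t(S)))
})

test_that("k-means recovers well-separated groups and honors edge cases", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(10, mean = 0, sd = 0.05), ncol = 2),
               matrix(rnorm(10, mean = 5, sd = 0.05), ncol = 2))
  rownames(pts) <- paste0("p", 1:10)
  for (seed in c(0, 1, 7)) {
    cl <- kmeans_cluster(pts, k = 2, seed = seed)
    expect_equal(length(unique(cl[1:5])), 1)
    expect_equal(length(unique(cl[6:10])), 1)
    expect_true(cl[1] != cl[6])
  }
  expect_equal(as.integer(kmeans_cluster(pts, k = 1)), rep(0L, 10))
  cl_all <- kmeans_cluster(pts + matrix(runif(20), ncol = 2), k = 10)
  expect_equal(length(unique(cl_all)), 10)   # one point per cluster
  # partition invariant
  cl5 <- kmeans_cluster(pts, k = 5, seed = 3)
  expect_equal(sum(attr(cl5, "sizes")), nrow(pts))
  # determinism given seed
  expect_identical(kmeans_cluster(pts, k = 3, seed = 4),
                   kmeans_cluster(pts, k = 3, seed = 4))
})

test_that("largest cluster extraction takes the most populous cluster", {
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- paste0("r", 1:10)
  cl <- structure(setNames(c(rep(0L, 3), rep(1L, 5), rep(2L, 2)),
                           paste0("r", 1:10)),
                  class = "cluster_assignment", k = 3L, seed = 0L,
                  k_reduced = FALSE, sizes = c(3L, 5L, 2L))
  sub <- largest_cluster_subgraph(g, cl)
  expect_setequal(igraph::V(sub)$name, paste0("r", 4:8))
  expect_false(igraph::graph_attr(sub, "size_tie"))
  # tie goes to the lower index and is flagged
  cl2 <- structure(setNames(rep(c(0L, 1L), 5), paste0("r", 1:10)),
                   class = "cluster_assignment", k = 2L, seed = 0L,
                   k_reduced = FALSE, sizes = c(5L, 5L))
  sub2 <- largest_cluster_subgraph(g, cl2)
  expect_equal(igraph::graph_attr(sub2, "cluster"), 0L)
  expect_true(igraph::graph_attr(sub2, "size_tie"))
  # brute-force node filter oracle
  expect_setequal(igraph::V(sub2)$name, names(cl2)[cl2 == 0])
})

test_that("SIF and GraphML exports round-trip for Cytoscape", {
  m <- generate_model(synthetic_spec(n_metabolites = 8,
                                     n_internal_reactions = 10, seed = 5))
  g <- build_reaction_graph(m)
  dir <- withr::local_tempdir()

  sif <- file.path(dir, "g.sif")
  export_graph(g, sif, format = "sif")
  lines <- readLines(sif)
  expect_equal(sum(grepl("shares_metabolite", lines)), igraph::ecount(g))

  gml <- file.path(dir, "g.graphml")
  export_graph(g, gml, format = "graphml")
  g2 <- read_graphml(gml)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_setequal(graph_edge_keys(g2), graph_edge_keys(g))
  ends1 <- graph_edge_keys(g)
  expect_equal(igraph::E(g2)$shared[order(graph_edge_keys(g2))],
               igraph::E(g)$shared[order(ends1)])

  # single-edge graph gives exactly one SIF line; isolated nodes get
  # bare node lines
  g1 <- igraph::make_graph(c("a", "b"), directed = FALSE)
  g1 <- igraph::add_vertices(g1, 1, name = "lonely")
  f1 <- file.path(dir, "one.sif")
  export_graph(g1, f1, format = "sif")
  expect_equal(readLines(f1), c("a shares_metabolite b", "lonely"))
  expect_error(export_graph(g1, "/no/such/dir/x.sif", "sif"), "directory")
})
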