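named_ring <- function(n) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- paste0("r", seq_len(n))
  g
}

random_named_graph <- function(n, p = 0.15) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# direct linear-solver oracle for the unnormalized fixed point
# (I - d L) r = (1 - d) 1
oracle_rank <- function(lm, d) {
  L <- as.matrix(lm$L)
  n <- ncol(L)
  setNames(as.numeric(solve(diag(n) - d * L, rep(1 - d, n))), colnames(L))
}

test_that("link matrix columns are degree-normalized", {
  g2 <- igraph::make_graph(c("a", "b"), directed = FALSE)
  lm <- link_matrix(g2)
  expect_equal(as.matrix(lm$L), matrix(c(0, 1, 1, 0), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b"))))
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  Lt <- as.matrix(link_matrix(tri)$L)
  expect_true(all(Lt[Lt != 0] == 0.5))
  expect_equal(unname(colSums(Lt)), rep(1, 3))
})

test_that("non-dangling column sums are 1 and isolated nodes are flagged", {
  set.seed(3)
  for (i in 1:20) {
    g <- random_named_graph(sample(5:30, 1))
    lm <- link_matrix(g)
    cs <- Matrix::colSums(lm$L)
    expect_equal(unname(cs[!lm$dangling]),
                 rep(1, sum(!lm$dangling)))
    expect_equal(unname(cs[lm$dangling]), rep(0, sum(lm$dangling)))
    expect_equal(unname(lm$dangling),
                 unname(igraph::degree(g) == 0))
  }
})

test_that("edgeless graphs settle at the bare teleport value", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("r", 1:4)
  r <- pagerank(g, d = 0.85)
  expect_equal(as.numeric(r), rep(0.15, 4))
})

test_that("a symmetric pair reaches the fixed point P = 1", {
  g <- igraph::make_graph(c("a", "b"), directed = FALSE)
  r <- pagerank(g)
  expect_equal(as.numeric(r), c(1, 1), tolerance = 1e-9)
})

test_that("power iteration matches the direct linear solve", {
  set.seed(17)
  for (i in 1:25) {
    g <- random_named_graph(sample(5:50, 1))
    lm <- link_matrix(g)
    r <- pagerank(lm, d = 0.85, tol = 1e-12)
    expect_equal(unclass(r), oracle_rank(lm, 0.85), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # fixed-point residual
    resid <- max(abs(unclass(r) - (0.15 + 0.85 * as.numeric(lm$L %*% r))))
    expect_lt(resid, 1e-11)
    # every rank at least the teleport floor
    expect_true(all(unclass(r) >= 0.15 - 1e-12))
  }
})

test_that("normalized variant agrees with igraph's PageRank", {
  set.seed(23)
  g <- random_named_graph(30, p = 0.2)
  r <- pagerank(g, d = 0.85, tol = 1e-13, normalized = TRUE)
  ref <- igraph::page_rank(g, damping = 0.85)$vector
  expect_equal(unclass(r), ref, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(r), 1, tolerance = 1e-9)
})

test_that("ranks collapse to the teleport term as d -> 0", {
  g <- named_ring(6)
  r <- pagerank(g, d = 1e-6)
  expect_equal(as.numeric(r), rep(1 - 1e-6, 6), tolerance = 1e-5)
})

test_that("combined scores are elementwise rank times |flux|", {
  p <- setNames(c(1, 0.15, 2), c("a", "b", "c"))
  v <- setNames(c(0, 2, -3), c("a", "b", "c"))
  z <- combined_score(p, v)
  expect_equal(as.numeric(z), c(0, 0.3, 6))
  set.seed(4)
  for (i in 1:20) {
    ids <- paste0("r", 1:10)
    p <- setNames(runif(10, 0.15, 3), ids)
    v <- setNames(rnorm(10), ids)
    z <- combined_score(p, v)
    loop <- vapply(ids, function(k) p[[k]] * abs(v[[k]]), numeric(1))
    expect_equal(unclass(z), loop, ignore_attr = TRUE)
  }
  expect_error(combined_score(p, v[-1], restrict = names(p)), "r1")
})

test_that("selection sorts by score with lexicographic tie-break", {
  z <- setNames(c(3, 1, 2), c("x", "y", "w"))
  top <- select_significant(z, top_n = 2)
  expect_equal(top$reaction, c("x", "w"))
  expect_equal(top$rank, 1:2)
  none <- select_significant(z, min_score = 10)
  expect_equal(nrow(none), 0)
  tied <- select_significant(setNames(c(1, 1, 0.5), c("b", "a", "c")),
                             top_n = 2)
  expect_equal(tied$reaction, c("a", "b"))
  expect_true(attr(tied, "ties"))
  expect_error(select_significant(z, top_n = 0), "positive")
  expect_error(select_significant(z), "exactly one")
  expect_error(select_significant(z, top_n = 1, min_score = 1), "exactly one")
})
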