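mk_iv <- function(ids, lo, hi, cond = "x") {
  structure(data.frame(reaction = ids, v_min = lo, v_max = hi,
                       stringsAsFactors = FALSE),
            class = c("flux_intervals", "data.frame"), condition = cond)
}

test_that("interval overlap and shift follow interval arithmetic", {
  d <- compare_intervals(mk_iv("r", 0, 5), mk_iv("r", 0, 5))
  expect_equal(d$overlap, 1)
  expect_equal(d$shift, 0)
  expect_false(d$significant)

  d2 <- compare_intervals(mk_iv("r", 0, 2), mk_iv("r", 3, 5))
  expect_equal(d2$overlap, 0)
  expect_true(d2$significant)

  d3 <- compare_intervals(mk_iv("r", 0, 4), mk_iv("r", 2, 6))
  expect_equal(d3$overlap, 2 / 6)

  # numeric-grid cross-check of the Jaccard value
  grid <- seq(0, 6, by = 1e-3)
  expect_equal(d3$overlap,
               sum(grid >= 2 & grid <= 4) / sum(grid >= 0 & grid <= 6),
               tolerance = 1e-3)
})

test_that("zero-width intervals compare by the stated convention", {
  expect_equal(compare_intervals(mk_iv("r", 2, 2), mk_iv("r", 2, 2))$overlap, 1)
  d <- compare_intervals(mk_iv("r", 2, 2), mk_iv("r", 3, 3))
  expect_equal(d$overlap, 0)
  expect_equal(d$shift, Inf)
  expect_true(d$significant)
})

test_that("overlap is symmetric under swapping conditions", {
  set.seed(5)
  for (i in 1:50) {
    a <- sort(runif(2, -3, 3)); b <- sort(runif(2, -3, 3))
    d1 <- compare_intervals(mk_iv("r", a[1], a[2]), mk_iv("r", b[1], b[2]))
    d2 <- compare_intervals(mk_iv("r", b[1], b[2]), mk_iv("r", a[1], a[2]))
    expect_equal(d1$overlap, d2$overlap)
    expect_equal(d1$shift, d2$shift)
  }
})

test_that("mismatched reaction sets fail listing the symmetric difference", {
  expect_error(compare_intervals(mk_iv(c("a", "b"), 0, 1),
                                 mk_iv(c("a", "z"), 0, 1)),
               "b, z")
})

test_that("consensus is the strict intersection across pairs", {
  mk_div <- function(ids, sig) {
    structure(data.frame(reaction = ids, overlap = 0, shift = 0,
                         significant = sig, stringsAsFactors = FALSE),
              class = c("interval_divergence", "data.frame"))
  }
  d1 <- mk_div(c("A", "B", "C"), c(TRUE, TRUE, FALSE))
  d2 <- mk_div(c("A", "B", "C"), c(FALSE, TRUE, TRUE))
  expect_equal(consensus_over_pairs(list(d1, d2)), "B")
  expect_setequal(consensus_over_pairs(list(d1)), c("A", "B"))
  expect_error(consensus_over_pairs(list()), "non-empty")
  # fold-left intersection oracle on random significance patterns
  set.seed(9)
  ids <- paste0("r", 1:8)
  for (i in 1:20) {
    divs <- lapply(1:3, function(k) mk_div(ids, runif(8) < 0.5))
    brute <- ids
    for (d in divs) brute <- brute[brute %in% d$reaction[d$significant]]
    expect_equal(consensus_over_pairs(divs), brute)
  }
})

test_that("biomarker extraction reports genes and metabolites per reaction", {
  tab <- significant_reaction_table()
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    genes <- strsplit(tab$genes[i], " ")[[1]]
    parse_reaction_equation(tab$equation[i], id = tab$index[i],
                            gene_rule = paste(genes, collapse = " OR "))
  })
  m <- metabolic_model(rxns, id = "curated")

  rep1 <- extract_biomarkers(m, "3161")
  expect_setequal(rep1$genes$gene, c("UPP1", "UPP2"))
  expect_setequal(rep1$metabolites$metabolite,
                  c("pi[c]", "uri[c]", "r1p[c]", "ura[c]"))

  rep2 <- extract_biomarkers(m, "3474")
  expect_setequal(rep2$genes$gene, c("SDHD", "SDHC", "SDHB", "SDHA"))
  expect_equal(length(rep2$metabolites$metabolite), 4)
  expect_true(all(grepl("\\[m\\]$", rep2$metabolites$metabolite)))

  empty <- extract_biomarkers(m, character())
  expect_equal(length(empty$reactions), 0)
  expect_equal(nrow(empty$genes), 0)
  expect_error(extract_biomarkers(m, "nope"), "nope")
})

test_that("every reported gene traces back to a listed reaction", {
  m <- generate_model(synthetic_spec(seed = 4))
  ids <- m$reactions$id[1:5]
  rep <- extract_biomarkers(m, ids)
  expect_true(all(rep$genes$reaction %in% ids))
  for (r in ids) {
    expect_setequal(rep$genes$gene[rep$genes$reaction == r],
                    genes_in_rule(m$reactions$gene_rule[m$reactions$id == r]))
  }
})

test_that("a directly planted disjoint bound shift is always recovered", {
  for (seed in 1:10) {
    sp <- synthetic_spec(n_metabolites = 10, n_internal_reactions = 14,
                         seed = seed)
    m <- generate_model(sp)
    iv_n <- flux_interval(m, fix_objective = NULL)
    dis <- m
    # pin one chain reaction far outside its normal range
    j <- which(m$reactions$id == "R01")
    dis$reactions$lower_bound[j] <- 20
    dis$reactions$upper_bound[j] <- 25
    iv_d <- mk_iv(iv_n$reaction, iv_n$v_min, iv_n$v_max)
    iv_d$v_min[j] <- 20; iv_d$v_max[j] <- 25
    d <- compare_intervals(iv_n, iv_d)
    expect_true("R01" %in% d$reaction[d$significant])
  }
})
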