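# Exhaustive oracle for GPR evaluation: enumerate the rule tree directly
# over every subset of measured genes (rules <= 4 genes).
oracle_eval <- function(rule_text, levels) {
  # recursive min/max on a freshly parsed tree, written independently of
  # eval_gene_rule's traversal (explicit stack-free recursion over tokens
  # would be overkill; instead evaluate by substituting into R logic)
  f <- function(node) {
    if (node$op == "gene")
      return(if (node$gene %in% names(levels)) levels[[node$gene]] else NULL)
    vals <- lapply(node$args, f)
    if (node$op == "and") {
      if (any(vapply(vals, is.null, TRUE))) return(NULL)
      return(min(unlist(vals)))
    }
    vals <- vals[!vapply(vals, is.null, TRUE)]
    if (length(vals) == 0) return(NULL)
    max(unlist(vals))
  }
  out <- f(parse_gene_rule(rule_text))
  if (is.null(out)) NA_real_ else out
}

test_that("gene rules evaluate with AND = min, OR = max, missing handled", {
  expect_equal(eval_gene_rule("g1", c(g1 = 7)), 7)
  expect_equal(eval_gene_rule("g1 AND g2", c(g1 = 3, g2 = 5)), 3)
  expect_equal(eval_gene_rule("g1 OR g2", c(g2 = 5)), 5)          # g1 missing
  expect_true(is.na(eval_gene_rule("g1 AND g2", c(g2 = 5))))      # AND gap
  expect_true(is.na(eval_gene_rule("", c(g1 = 1))))               # empty rule
  expect_equal(eval_gene_rule("(g1 AND g2) OR g3",
                              c(g1 = 2, g2 = 8, g3 = 4)), 4)
})

test_that("rule evaluation matches an independent oracle with missing genes", {
  set.seed(11)
  rules <- c("a", "a AND b", "a OR b", "(a AND b) OR c", "a AND (b OR c)",
             "a OR b OR c", "a AND b AND c", "(a OR b) AND (c OR d)")
  for (rule in rules) {
    genes <- genes_in_rule(rule)
    for (rep in 1:20) {
      present <- genes[runif(length(genes)) < 0.7]
      lv <- setNames(round(runif(length(present)) * 10, 2), present)
      expect_equal(eval_gene_rule(rule, lv), oracle_eval(rule, lv),
                   info = paste(rule, "|", paste(present, collapse = ",")))
    }
  }
})

test_that("gene order within a rule never changes the reaction score", {
  lv <- c(g1 = 2, g2 = 9, g3 = 5)
  expect_equal(eval_gene_rule("g1 OR g2 OR g3", lv),
               eval_gene_rule("g3 OR g1 OR g2", lv))
  expect_equal(eval_gene_rule("(g1 AND g2) OR g3", lv),
               eval_gene_rule("g3 OR (g2 AND g1)", lv))
})

test_that("activity classes follow score quantiles and p_active is a CDF rank", {
  scores <- setNames(as.numeric(1:10), paste0("r", 1:10))
  st <- classify_activity(scores, q_low = 0.25, q_high = 0.75)
  expect_equal(st$reaction[st$activity_class == "low"], c("r1", "r2"))
  expect_equal(st$reaction[st$activity_class == "high"], c("r9", "r10"))
  expect_equal(st$p_active, (1:10 - 1) / 9)
  # monotone nondecreasing in score
  expect_true(all(diff(st$p_active[order(st$score)]) >= 0))
})

test_that("degenerate score distributions fall back to intermediate/0.5", {
  tied <- classify_activity(setNames(rep(2, 5), paste0("r", 1:5)))
  expect_true(all(tied$activity_class == "intermediate"))
  expect_true(all(tied$p_active == 0.5))
  single <- classify_activity(c(r1 = 3, r2 = NA))
  expect_equal(single$p_active[1], 0.5)
  expect_equal(single$activity_class, c("intermediate", "unobserved"))
  expect_error(classify_activity(c(a = NA_real_)), "unobserved")
})

test_that("unobserved reactions are exactly those with no measured gene", {
  m <- chain_model()
  prof <- expression_profile(c(g1 = 4, g3 = 6), "normal")
  sc <- reaction_expression(m, prof)
  expect_equal(unname(is.na(sc)), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sc[["R_AB"]], 4)
  expect_equal(sc[["R_BC"]], 6)   # g2 missing, OR takes g3
  st <- classify_activity(sc)
  expect_equal(st$activity_class[is.na(st$p_active)],
               rep("unobserved", 2))
})

test_that("expression TSVs round-trip through read_expression", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tvalue", "g1\t3.5", "g2\t0"), f)
  p <- read_expression(f, "disease/rep1")
  expect_equal(p$levels, c(g1 = 3.5, g2 = 0))
  expect_equal(p$condition, "disease/rep1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\t1.25", "g2\t2"), f2)   # headerless
  expect_equal(read_expression(f2, "n")$levels, c(g1 = 1.25, g2 = 2))
  expect_error(expression_profile(c(g1 = -1), "n"), ">= 0")
})
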