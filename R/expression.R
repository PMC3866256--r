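# Condition-specific expression: map gene levels onto reactions through
# their GPR rules, then convert reaction scores to an activity probability
# (empirical CDF rank) and a high/low/intermediate class.

#' Construct an expression profile
#'
#' @param levels named numeric vector of nonnegative gene expression
#'   levels (platform units; assumed pre-processed).
#' @param condition condition label, e.g. `"normal"` or `"disease"`,
#'   optionally with a replicate tag (`"disease/rep1"`).
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(levels, condition) {
  stopifnot(is.numeric(levels), !is.null(names(levels)),
            all(nzchar(names(levels))),
            is.character(condition), length(condition) == 1,
            nzchar(condition))
  if (any(!is.finite(levels)) || any(levels < 0))
    stop("expression levels must be finite and >= 0")
  structure(list(condition = condition, levels = levels),
            class = "expression_profile")
}

#' Read a two-column expression TSV
#'
#' Expects tab-separated `gene_id<TAB>value` rows; a header line is
#' detected and skipped if the second field is non-numeric.
#'
#' @param path file path.
#' @param condition condition label for the profile.
#' @return an [expression_profile()].
#' @export
read_expression <- function(path, condition) {
  if (!file.exists(path)) stop("no such expression file: ", path)
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- ncol(first) >= 2 && is.na(suppressWarnings(as.numeric(first[[2]])))
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs two columns: ", path)
  expression_profile(setNames(as.numeric(tab[[2]]), as.character(tab[[1]])),
                     condition)
}

#' Map expression levels onto reactions
#'
#' Evaluates each reaction's gene rule against the profile with AND =
#' minimum and OR = maximum ([eval_gene_rule()]).  Reactions whose rule is
#' empty, or whose rule cannot be evaluated because every informative gene
#' is unmeasured, score `NA` (unobserved).
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile`.
#' @return named numeric vector, one score per reaction (NA = unobserved).
#' @export
reaction_expression <- function(model, profile) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(profile, "expression_profile"))
  setNames(vapply(model$reactions$gene_rule, eval_gene_rule, numeric(1),
                  levels = profile$levels, USE.NAMES = FALSE),
           model$reactions$id)
}

#' Classify reaction activity from expression scores
#'
#' Converts reaction expression scores into a probability of being active,
#' `p_active`, defined as the normalized empirical CDF rank
#' `(rank - 1) / (n - 1)` over the observed scores (average ranks for
#' ties), so the least-expressed reaction gets exactly 0, the most
#' expressed exactly 1, and the probability is scale-free across
#' expression platforms.  Degenerate distributions (all scores tied, or a
#' single observed reaction) get `p_active = 0.5`.  Reactions scoring
#' strictly below the `q_low` empirical quantile of the observed scores
#' are classed `low`, strictly above the `q_high` quantile `high`, the
#' rest `intermediate`; reactions with no measured gene are `unobserved`
#' and get `p_active = NA`.
#'
#' @param scores named numeric vector from [reaction_expression()].
#' @param q_low,q_high class thresholds, `0 <= q_low < q_high <= 1`.
#' @param condition optional condition label carried into the result.
#' @return object of class `reaction_activity`: a data frame with columns
#'   `reaction`, `score`, `p_active`, `activity_class`.
#' @export
classify_activity <- function(scores, q_low = 0.25, q_high = 0.75,
                              condition = NULL) {
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            q_low >= 0, q_high <= 1, q_low < q_high)
  obs <- !is.na(scores)
  if (!any(obs)) stop("all reaction scores are unobserved")
  p <- rep(NA_real_, length(scores))
  n <- sum(obs)
  p[obs] <- if (n == 1) 0.5 else
    (rank(scores[obs], ties.method = "average") - 1) / (n - 1)
  cls <- rep("unobserved", length(scores))
  cls[obs] <- "intermediate"
  lo_cut <- stats::quantile(scores[obs], q_low, type = 1, names = FALSE)
  hi_cut <- stats::quantile(scores[obs], q_high, type = 1, names = FALSE)
  cls[obs & scores < lo_cut] <- "low"
  cls[obs & scores > hi_cut] <- "high"
  out <- data.frame(reaction = names(scores), score = unname(scores),
                    p_active = p, activity_class = cls,
                    stringsAsFactors = FALSE)
  structure(out, class = c("reaction_activity", "data.frame"),
            q_low = q_low, q_high = q_high, condition = condition)
}

#' @export
print.reaction_activity <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("<reaction_activity>", if (!is.null(cond)) cond, "-",
      nrow(x), "reactions (",
      sum(x$activity_class == "high"), "high /",
      sum(x$activity_class == "low"), "low /",
      sum(x$activity_class == "unobserved"), "unobserved )\n")
  print.data.frame(utils::head(x, 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}
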