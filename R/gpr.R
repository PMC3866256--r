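# Gene-protein-reaction (GPR) boolean rules: "g1 AND g2", "(a AND b) OR c".
# AND = enzyme complex (all subunits required), OR = isozymes (any suffices).

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean gene association such as `"(g1 AND g2) OR g3"` into an
#' expression tree.  `AND`/`OR` are case-insensitive; `&`/`&&` and `|`/`||`
#' are accepted as aliases.  An empty or whitespace-only rule yields `NULL`
#' (no gene association).
#'
#' @param text character scalar, the rule.
#' @return A nested list with elements `op` (`"gene"`, `"and"` or `"or"`)
#'   and either `gene` (a gene id) or `args` (sub-trees), or `NULL` for an
#'   empty rule.
#' @examples
#' parse_gene_rule("(UPP1 OR UPP2)")
#' @export
parse_gene_rule <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("gene rule parse error: unexpected token '", st$toks[st$pos],
         "' in rule: ", text, call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("&&|&", " AND ", text)
  text <- gsub("\\|\\||\\|", " OR ", text)
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && toupper(tk) == "OR") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && toupper(tk) == "AND") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("gene rule parse error: unexpected end of rule", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("gene rule parse error: missing ')'", call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || toupper(tk) %in% c("AND", "OR"))
    stop("gene rule parse error: unexpected token '", tk, "'", call. = FALSE)
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Genes referenced by a gene rule
#'
#' @param rule a rule string or a tree from [parse_gene_rule()].
#' @return character vector of unique gene ids (empty for an empty rule).
#' @export
genes_in_rule <- function(rule) {
  if (is.character(rule)) rule <- parse_gene_rule(rule)
  if (is.null(rule)) return(character())
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$args, genes_in_rule)))
}

#' Evaluate a gene rule against expression levels
#'
#' AND maps to the minimum of its branches (complex limited by its scarcest
#' subunit) and OR to the maximum (isozymes are interchangeable).  A gene
#' absent from `levels` is skipped inside OR; inside AND it makes the whole
#' branch unobserved (`NA`).
#'
#' @param rule rule string or parsed tree.
#' @param levels named numeric vector of gene expression levels.
#' @return numeric scalar, or `NA` if the rule is empty/unobserved.
#' @export
eval_gene_rule <- function(rule, levels) {
  if (is.character(rule)) rule <- parse_gene_rule(rule)
  if (is.null(rule)) return(NA_real_)
  switch(rule$op,
    gene = if (rule$gene %in% names(levels)) unname(levels[rule$gene]) else NA_real_,
    and = {
      vals <- vapply(rule$args, eval_gene_rule, numeric(1), levels = levels)
      if (anyNA(vals)) NA_real_ else min(vals)
    },
    or = {
      vals <- vapply(rule$args, eval_gene_rule, numeric(1), levels = levels)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) NA_real_ else max(vals)
    },
    stop("invalid gene rule node")
  )
}
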