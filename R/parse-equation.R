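# Bracketed reaction-equation dialect, e.g. "[c]:pi+uri <=> r1p+ura" or
# "h2o[x] + prpncoa[x] -> 3hpcoa[x]".  A leading "[c]:" assigns compartment
# c to every participant without an explicit suffix; "(2) met" or "2 met"
# gives a stoichiometric quantity; unicode arrows are emitted on output,
# ASCII aliases accepted on input.

ARROW_REV <- "⇆"   # reversible
ARROW_IRR <- "→"   # irreversible

#' Parse a reaction-equation string
#'
#' Parses the bracketed reaction dialect into a [reaction()] object.
#' The reversible arrow (`⇆`, alias `<=>` or `<==>`) sets
#' `reversible = TRUE` and default bounds `[-default_bound, default_bound]`;
#' the irreversible arrow (`→`, alias `->` or `-->`) gives
#' `[0, default_bound]`.
#'
#' @param text equation string.
#' @param id optional reaction id (defaults to the equation string itself).
#' @param gene_rule optional gene association string.
#' @param default_bound flux capacity used for the default bounds.
#' @return A `reaction` object; substrates carry negative and products
#'   positive coefficients.
#' @examples
#' parse_reaction_equation("[c]:pi+uri <=> r1p+ura")
#' @export
parse_reaction_equation <- function(text, id = NULL, gene_rule = "",
                                    default_bound = 1000) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- trimws(text)

  # global compartment prefix "[c]:"
  default_comp <- NA_character_
  m <- regmatches(raw, regexec("^\\[([^]\\s]+)\\]\\s*:\\s*", raw))[[1]]
  if (length(m)) {
    default_comp <- m[2]
    check_compartment(default_comp, text)
    raw <- substring(raw, nchar(m[1]) + 1L)
  }

  arrows <- c(ARROW_REV, "<==>", "<=>", ARROW_IRR, "-->", "->")
  arrow <- NULL
  for (a in arrows) {
    if (grepl(a, raw, fixed = TRUE)) { arrow <- a; break }
  }
  if (is.null(arrow))
    stop("malformed reaction equation (no arrow '", ARROW_REV, "'/'<=>' or '",
         ARROW_IRR, "'/'->'): ", text, call. = FALSE)
  sides <- strsplit(raw, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2 || grepl(arrow, sides[2], fixed = TRUE))
    stop("malformed reaction equation (expected exactly one arrow): ", text,
         call. = FALSE)
  reversible <- arrow %in% c(ARROW_REV, "<=>", "<==>")

  lhs <- parse_equation_side(sides[1], default_comp, text, "left")
  rhs <- parse_equation_side(sides[2], default_comp, text, "right")
  lhs$coefficient <- -lhs$coefficient
  participants <- rbind(lhs, rhs)

  key <- paste0(participants$metabolite, "[", participants$compartment, "]")
  if (anyDuplicated(key))
    stop("participant '", key[duplicated(key)][1],
         "' appears twice in reaction equation: ", text, call. = FALSE)

  reaction(id = if (is.null(id)) text else id,
           participants = participants,
           reversible = reversible,
           lower_bound = if (reversible) -default_bound else 0,
           upper_bound = default_bound,
           gene_rule = gene_rule)
}

parse_equation_side <- function(side, default_comp, text, which_side) {
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0)
    stop("empty ", which_side, " side in reaction equation: ", text,
         call. = FALSE)
  rows <- lapply(terms, parse_equation_term, default_comp = default_comp,
                 text = text)
  do.call(rbind, rows)
}

parse_equation_term <- function(term, default_comp, text) {
  coef <- 1
  # "(2) met", "2 met" or "2.5 met"
  m <- regmatches(term, regexec("^\\(\\s*([0-9.]+)\\s*\\)\\s*(.+)$", term))[[1]]
  if (!length(m))
    m <- regmatches(term, regexec("^([0-9.]+)\\s+(.+)$", term))[[1]]
  if (length(m)) {
    coef <- as.numeric(m[2])
    term <- trimws(m[3])
  }
  # explicit compartment suffix "met[c]"
  comp <- default_comp
  m <- regmatches(term, regexec("^(.*)\\[([^]]+)\\]$", term))[[1]]
  if (length(m)) {
    term <- trimws(m[2])
    comp <- m[3]
    check_compartment(comp, text)
  }
  if (is.na(comp))
    stop("metabolite '", term, "' has no compartment (no suffix and no '[c]:'",
         " prefix) in reaction equation: ", text, call. = FALSE)
  if (!grepl("^[A-Za-z0-9_][A-Za-z0-9_'\\-]*$", term))
    stop("malformed metabolite token '", term, "' in reaction equation: ",
         text, call. = FALSE)
  if (!is.finite(coef) || coef <= 0)
    stop("invalid stoichiometric quantity for '", term, "' in: ", text,
         call. = FALSE)
  data.frame(metabolite = term, compartment = comp, coefficient = coef,
             stringsAsFactors = FALSE)
}

check_compartment <- function(comp, text) {
  if (!grepl("^[a-z]$", comp))
    stop("unknown compartment '", comp, "' (expected a single lowercase ",
         "letter) in reaction equation: ", text, call. = FALSE)
  invisible(comp)
}

#' Serialize a reaction to the equation dialect
#'
#' Inverse of [parse_reaction_equation()].  When all participants share one
#' compartment the compact `[c]:` prefix form is emitted, otherwise each
#' metabolite carries its suffix.  Unit quantities are omitted; other
#' quantities are written as `(q)`.  Unicode arrows are always emitted.
#'
#' @param rxn a `reaction` object.
#' @return equation string.
#' @export
format_reaction_equation <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  p <- rxn$participants
  one_comp <- length(unique(p$compartment)) == 1
  fmt <- function(rows) {
    paste(vapply(seq_len(nrow(rows)), function(i) {
      q <- abs(rows$coefficient[i])
      qs <- if (isTRUE(all.equal(q, 1))) "" else paste0("(", format(q), ") ")
      suf <- if (one_comp) "" else paste0("[", rows$compartment[i], "]")
      paste0(qs, rows$metabolite[i], suf)
    }, character(1)), collapse = "+")
  }
  subs <- p[p$coefficient < 0, , drop = FALSE]
  prods <- p[p$coefficient > 0, , drop = FALSE]
  arrow <- if (rxn$reversible) paste0(" ", ARROW_REV, " ") else ARROW_IRR
  body <- paste0(fmt(subs), arrow, fmt(prods))
  if (one_comp) paste0("[", p$compartment[1], "]:", body) else body
}
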