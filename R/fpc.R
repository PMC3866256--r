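# Flux profile comparison: interval divergence between conditions,
# consensus across expression pairs, and biomarker extraction.

#' Compare normal and disease flux intervals
#'
#' For each reaction, computes the Jaccard overlap of its two intervals
#' (intersection length over union length; two zero-width intervals
#' overlap 1 if they are the same point, else 0) and the midpoint shift
#' `|mid_n - mid_d| / pooled width`, where the pooled width is the mean of
#' the two interval widths (0/0 is taken as 0, a nonzero shift over zero
#' pooled width as `Inf`).  A reaction is significant when
#' `overlap < theta_overlap` or `shift > theta_shift`.
#'
#' @param normal,disease `flux_intervals` over the same reaction set.
#' @param theta_overlap overlap threshold; identical intervals (overlap 1)
#'   are never significant at the default 0.2.
#' @param theta_shift shift threshold; disjoint intervals are always
#'   significant regardless of shift.
#' @return object of class `interval_divergence`: data frame with columns
#'   `reaction`, `overlap`, `shift`, `significant`.
#' @export
compare_intervals <- function(normal, disease, theta_overlap = 0.2,
                              theta_shift = 1.0) {
  stopifnot(inherits(normal, "flux_intervals"),
            inherits(disease, "flux_intervals"))
  sd_ <- setdiff(normal$reaction, disease$reaction)
  ds_ <- setdiff(disease$reaction, normal$reaction)
  if (length(sd_) || length(ds_))
    stop("interval sets cover different reactions; symmetric difference: ",
         paste(c(sd_, ds_), collapse = ", "))
  d <- disease[match(normal$reaction, disease$reaction), ]

  lo_n <- normal$v_min; hi_n <- normal$v_max
  lo_d <- d$v_min; hi_d <- d$v_max
  inter <- pmax(0, pmin(hi_n, hi_d) - pmax(lo_n, lo_d))
  uni <- pmax(hi_n, hi_d) - pmin(lo_n, lo_d)
  overlap <- ifelse(uni > 0, inter / uni,
                    as.numeric(abs((lo_n + hi_n) - (lo_d + hi_d)) < 1e-12))
  pooled <- ((hi_n - lo_n) + (hi_d - lo_d)) / 2
  mid_diff <- abs((lo_n + hi_n) / 2 - (lo_d + hi_d) / 2)
  shift <- ifelse(pooled > 0, mid_diff / pooled,
                  ifelse(mid_diff > 0, Inf, 0))
  out <- data.frame(reaction = normal$reaction, overlap = overlap,
                    shift = shift,
                    significant = overlap < theta_overlap | shift > theta_shift,
                    stringsAsFactors = FALSE)
  structure(out, class = c("interval_divergence", "data.frame"),
            theta_overlap = theta_overlap, theta_shift = theta_shift)
}

#' @export
print.interval_divergence <- function(x, ...) {
  cat("<interval_divergence>", nrow(x), "reactions,",
      sum(x$significant), "significant (theta_overlap =",
      attr(x, "theta_overlap"), ", theta_shift =", attr(x, "theta_shift"),
      ")\n")
  print.data.frame(utils::head(x[order(x$overlap), ], 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Consensus of significant reactions over expression pairs
#'
#' Returns the reactions flagged significant in *every* supplied
#' divergence result (strict set intersection), the consensus rule applied
#' across replicate normal/disease expression pairs.
#'
#' @param divergences list of `interval_divergence` objects.
#' @return character vector of reaction ids.
#' @export
consensus_over_pairs <- function(divergences) {
  if (!is.list(divergences) || length(divergences) == 0 ||
      inherits(divergences, "interval_divergence"))
    stop("supply a non-empty list of interval_divergence results")
  sets <- lapply(divergences, function(d) {
    stopifnot(inherits(d, "interval_divergence"))
    d$reaction[d$significant]
  })
  Reduce(intersect, sets)
}

#' Extract gene and metabolite biomarkers from selected reactions
#'
#' @param model a `metabolic_model`.
#' @param reactions character vector of selected reaction ids.
#' @return object of class `biomarker_report`: list with `reactions`,
#'   `genes` (data frame gene/reaction provenance), `metabolites` (data
#'   frame metabolite/reaction, compartment-qualified ids).
#' @export
extract_biomarkers <- function(model, reactions) {
  stopifnot(inherits(model, "metabolic_model"))
  reactions <- as.character(reactions)
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown))
    stop("unknown reaction id: ", paste(unknown, collapse = ", "))
  genes <- do.call(rbind, c(list(
    data.frame(gene = character(), reaction = character(),
               stringsAsFactors = FALSE)),
    lapply(reactions, function(r) {
      g <- genes_in_rule(model$reactions$gene_rule[model$reactions$id == r])
      if (length(g) == 0) return(NULL)
      data.frame(gene = g, reaction = r, stringsAsFactors = FALSE)
    })))
  mets <- do.call(rbind, c(list(
    data.frame(metabolite = character(), reaction = character(),
               stringsAsFactors = FALSE)),
    lapply(reactions, function(r) {
      col <- model$S[, match(r, model$reactions$id)]
      data.frame(metabolite = rownames(model$S)[which(col != 0)],
                 reaction = r, stringsAsFactors = FALSE)
    })))
  rownames(genes) <- rownames(mets) <- NULL
  structure(list(reactions = reactions, genes = genes, metabolites = mets),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("<biomarker_report>", length(x$reactions), "reactions,",
      length(unique(x$genes$gene)), "genes,",
      length(unique(x$metabolites$metabolite)), "metabolites\n")
  if (length(x$reactions)) {
    cat("  reactions:", paste(x$reactions, collapse = ", "), "\n")
    cat("  genes:", paste(unique(x$genes$gene), collapse = ", "), "\n")
    cat("  metabolites:", paste(unique(x$metabolites$metabolite),
                                collapse = ", "), "\n")
  }
  invisible(x)
}
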