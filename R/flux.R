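# Constraint-based flux analysis: expression-tightened condition models,
# flux balance analysis (FBA) and per-reaction flux intervals (FVA).

#' Default objective for a model
#'
#' The model's declared objective if present; otherwise a biomass reaction
#' (id matching "biomass", case-insensitive); otherwise the summed flux of
#' export-form exchange reactions (single participant consumed).
#'
#' @param model a `metabolic_model`.
#' @return named numeric vector of objective coefficients per reaction.
#' @export
default_objective <- function(model) {
  ids <- model$reactions$id
  if (!is.null(model$objective))
    return(setNames(as.numeric(model$objective), ids))
  obj <- setNames(numeric(length(ids)), ids)
  bm <- grepl("biomass", ids, ignore.case = TRUE)
  if (any(bm)) {
    obj[bm] <- 1
    return(obj)
  }
  n_part <- Matrix::colSums(model$S != 0)
  consumed <- Matrix::colSums(model$S) < 0
  exports <- ids[n_part == 1 & consumed]
  if (length(exports) == 0)
    stop("cannot infer an objective: no declared objective, biomass or ",
         "export exchange reaction")
  obj[exports] <- 1
  obj
}

#' Tighten a model's flux capacities by activity probability
#'
#' Builds the condition-specific LP model: mass-balance constraints are
#' unchanged, but each reaction's bounds are scaled by the factor
#' `tighten + (1 - tighten) * p_active`, interpolating linearly between the
#' floor `tighten` (probably-inactive reactions keep a small residual
#' capacity) and 1 (probably-active reactions keep their structural
#' capacity).  Unobserved reactions (`p_active = NA`) are left untouched;
#' structural bounds are never widened.
#'
#' @param model a `metabolic_model`.
#' @param state a `reaction_activity` from [classify_activity()], or `NULL`
#'   for no tightening.
#' @param tighten floor of the scaling factor, in (0, 1].
#' @return a `metabolic_model` with adjusted bounds; the applied factors are
#'   stored in attribute `"tighten_factors"` and the condition label in
#'   `"condition"`.
#' @export
build_condition_lp <- function(model, state = NULL, tighten = 0.1) {
  stopifnot(inherits(model, "metabolic_model"),
            tighten > 0, tighten <= 1)
  f <- setNames(rep(1, nrow(model$reactions)), model$reactions$id)
  condition <- NULL
  if (!is.null(state)) {
    stopifnot(inherits(state, "reaction_activity"))
    p <- setNames(state$p_active, state$reaction)
    p <- p[model$reactions$id]
    obs <- !is.na(p)
    f[obs] <- tighten + (1 - tighten) * p[obs]
    condition <- attr(state, "condition")
  }
  out <- model
  out$reactions$lower_bound <- model$reactions$lower_bound * f
  out$reactions$upper_bound <- model$reactions$upper_bound * f
  attr(out, "tighten_factors") <- f
  attr(out, "condition") <- condition
  out
}

#' Flux balance analysis
#'
#' Maximizes `objective' v` subject to the steady-state constraint
#' `S v = 0` and the model's flux bounds.
#'
#' @param model a `metabolic_model` (typically from [build_condition_lp()]).
#' @param objective numeric coefficient vector (named or positional, one
#'   per reaction); defaults to [default_objective()].
#' @return object of class `flux_profile`: list with `v` (named flux
#'   vector), `objective_value`, `objective`, `condition`.
#' @export
solve_fba <- function(model, objective = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  obj <- resolve_objective(model, objective)
  res <- solve_lp(obj = unname(obj), Aeq = as.matrix(model$S),
                  beq = rep(0, nrow(model$S)),
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound)
  lp_check(res, model)
  structure(list(v = setNames(res$x, model$reactions$id),
                 objective_value = res$value,
                 objective = obj,
                 condition = attr(model, "condition")),
            class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat("<flux_profile>", if (!is.null(x$condition)) x$condition,
      "- objective", format(x$objective_value),
      "-", sum(abs(x$v) > 1e-9), "of", length(x$v), "reactions active\n")
  invisible(x)
}

resolve_objective <- function(model, objective) {
  ids <- model$reactions$id
  if (is.null(objective)) return(default_objective(model))
  if (!is.null(names(objective))) {
    obj <- setNames(numeric(length(ids)), ids)
    unknown <- setdiff(names(objective), ids)
    if (length(unknown))
      stop("objective references unknown reaction: ",
           paste(unknown, collapse = ", "))
    obj[names(objective)] <- objective
    return(obj)
  }
  stopifnot(length(objective) == length(ids))
  setNames(as.numeric(objective), ids)
}

lp_check <- function(res, model) {
  if (res$status == "optimal") return(invisible())
  if (res$status == "infeasible") {
    f <- attr(model, "tighten_factors")
    extra <- if (!is.null(f) && any(f < 1)) {
      paste0("; expression-tightened reactions: ",
             paste(names(f)[f < 1], collapse = ", "))
    } else ""
    stop("flux model is infeasible", extra, call. = FALSE)
  }
  if (res$status == "maxit")
    stop("LP solver hit its iteration limit without converging",
         call. = FALSE)
  stop("LP solver failure: ", res$status, call. = FALSE)
}

#' Flux intervals (flux variability analysis)
#'
#' Computes, for each requested reaction, the minimum and maximum flux it
#' can carry over the constrained steady-state region.  When
#' `fix_objective` is given, the FBA optimum `z*` is computed first and the
#' constraint `objective' v >= fix_objective * z*` is appended, so the
#' intervals describe variability near optimal operation.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids (default: all).
#' @param fix_objective fraction of the FBA optimum to enforce, in (0, 1];
#'   `NULL` disables objective fixing.
#' @param objective objective coefficients (see [solve_fba()]).
#' @return object of class `flux_intervals`: data frame with columns
#'   `reaction`, `v_min`, `v_max`; attributes `condition`, `fix_objective`,
#'   `objective_value`.
#' @export
flux_interval <- function(model, reactions = NULL, fix_objective = 0.9,
                          objective = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- model$reactions$id
  if (is.null(reactions)) reactions <- ids
  unknown <- setdiff(reactions, ids)
  if (length(unknown))
    stop("unknown reaction id: ", paste(unknown, collapse = ", "))

  Aeq <- as.matrix(model$S)
  beq <- rep(0, nrow(Aeq))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(ids)

  ge <- NULL
  opt <- NA_real_
  obj <- resolve_objective(model, objective)
  if (!is.null(fix_objective)) {
    stopifnot(fix_objective > 0, fix_objective <= 1)
    fba <- solve_fba(model, objective = obj)
    opt <- fba$objective_value
    ge <- list(A = matrix(unname(obj), nrow = 1), b = fix_objective * opt)
  }

  v_min <- v_max <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    e <- numeric(n)
    e[match(reactions[k], ids)] <- 1
    hi <- solve_lp(e, Aeq, beq, lb, ub, ge = ge, maximize = TRUE)
    lo <- solve_lp(e, Aeq, beq, lb, ub, ge = ge, maximize = FALSE)
    lp_check(hi, model); lp_check(lo, model)
    v_max[k] <- hi$value
    v_min[k] <- lo$value
  }
  out <- data.frame(reaction = reactions, v_min = v_min, v_max = v_max,
                    stringsAsFactors = FALSE)
  structure(out, class = c("flux_intervals", "data.frame"),
            condition = attr(model, "condition"),
            fix_objective = fix_objective, objective_value = opt)
}

#' @export
print.flux_intervals <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("<flux_intervals>", if (!is.null(cond)) cond, "-", nrow(x),
      "reactions; objective fixed at",
      if (is.null(attr(x, "fix_objective"))) "none" else
        attr(x, "fix_objective"), "\n")
  print.data.frame(utils::head(x, 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}
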