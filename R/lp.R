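# Thin LP layer over boot::simplex.  Problems are stated on bounded
# variables (lb <= x <= ub, all finite); they are shifted to y = x - lb so
# the solver's x >= 0 convention applies, and constraint rows are sign-
# normalized to the solver's nonnegative right-hand-side requirement.

solve_lp <- function(obj, Aeq, beq, lb, ub, ge = NULL, maximize = TRUE,
                     eps = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("LP requires finite bounds (possible unbounded direction); ",
         "set default flux capacities on the model")
  if (any(lb > ub)) return(list(status = "infeasible"))

  # variables pinned by equal bounds are eliminated up front (the simplex
  # tableau does not tolerate zero-width columns)
  fixed <- (ub - lb) < 1e-12
  if (any(fixed)) {
    Aeq <- as.matrix(Aeq)
    x <- lb
    free <- !fixed
    if (!any(free)) {
      ok <- max(abs(Aeq %*% x - beq)) < 1e-9 &&
        (is.null(ge) || all(matrix(ge$A, ncol = n) %*% x >= ge$b - 1e-9))
      return(if (ok) list(status = "optimal", x = x, value = sum(obj * x))
             else list(status = "infeasible"))
    }
    beq2 <- beq - Aeq[, fixed, drop = FALSE] %*% lb[fixed]
    ge2 <- NULL
    if (!is.null(ge)) {
      A <- matrix(ge$A, ncol = n)
      ge2 <- list(A = A[, free, drop = FALSE],
                  b = ge$b - A[, fixed, drop = FALSE] %*% lb[fixed])
    }
    sub <- solve_lp(obj[free], Aeq[, free, drop = FALSE], as.numeric(beq2),
                    lb[free], ub[free], ge = ge2, maximize = maximize,
                    eps = eps)
    if (sub$status != "optimal") return(sub)
    x[free] <- sub$x
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }

  Aeq <- as.matrix(Aeq)
  b3 <- as.numeric(beq - Aeq %*% lb)
  flip <- b3 < 0
  if (any(flip)) {
    Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
    b3[flip] <- -b3[flip]
  }

  A1 <- diag(n)            # y <= ub - lb
  b1 <- ub - lb
  A2 <- NULL; b2 <- NULL
  if (!is.null(ge)) {
    A <- matrix(ge$A, ncol = n)
    b <- as.numeric(ge$b - A %*% lb)
    pos <- b >= 0
    if (any(pos)) { A2 <- A[pos, , drop = FALSE]; b2 <- b[pos] }
    if (any(!pos)) {       # A y >= b with b < 0  <=>  -A y <= -b
      A1 <- rbind(A1, -A[!pos, , drop = FALSE])
      b1 <- c(b1, -b[!pos])
    }
  }

  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = Aeq, b3 = b3, maxi = maximize,
                       n.iter = max(200L, 20L * (n + length(b1) + length(b3))),
                       eps = eps)
  if (res$solved == -1) return(list(status = "infeasible"))
  if (res$solved == 0) return(list(status = "maxit"))
  x <- as.numeric(res$soln)[seq_len(n)] + lb
  list(status = "optimal", x = x,
       value = sum(obj * x))
}
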