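## Linear-programming kernel.
##
## A dense two-phase primal simplex with Bland's anti-cycling rule. Metabolic
## steady-state LPs are heavily degenerate (many zero basic variables), which
## is why Bland's rule is used throughout: it guarantees termination at the
## cost of some speed, irrelevant at the problem sizes this package targets
## (tens to a few thousand reactions).
##
## Problems are given in the bounded form
##     max / min  obj' v
##     s.t.       Aeq v  = beq
##                Ale v <= ble
##                lb <= v <= ub        (bounds must be finite)
## and converted internally to standard form by the shift x = v - lb and by
## slack variables on the <= rows.

#' Solve a bounded linear program
#'
#' Exact dense simplex used by every optimization in the package. All bounds
#' must be finite; flux-balance models conventionally use +/-1000 mmol/gDCW/h
#' as "unbounded".
#'
#' @param obj numeric objective vector (length n).
#' @param Aeq equality constraint matrix (m x n), may have zero rows.
#' @param beq equality right-hand side (length m).
#' @param lb,ub finite lower/upper variable bounds (length n).
#' @param sense `"max"` or `"min"`.
#' @param Ale,ble optional inequality rows `Ale v <= ble`.
#' @param tol pivot tolerance.
#' @param max_iter iteration cap (errors if exceeded; indicates a bug, not a
#'   hard instance, since Bland's rule precludes cycling).
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `x` (solution in the original variables, `NULL` unless optimal) and
#'   `value` (objective value, `NA` unless optimal).
#' @keywords internal
solve_lp <- function(obj, Aeq, beq, lb, ub, sense = c("max", "min"),
                     Ale = NULL, ble = NULL, tol = 1e-9, max_iter = 50000L) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  Aeq <- as.matrix(Aeq)
  if (ncol(Aeq) != n) stop("Aeq has ", ncol(Aeq), " columns, expected ", n)

  ## shift x = v - lb >= 0; upper bounds become slack rows x <= ub - lb
  A1 <- diag(n)
  b1 <- ub - lb
  if (!is.null(Ale)) {
    Ale <- as.matrix(Ale)
    A1 <- rbind(A1, Ale)
    b1 <- c(b1, ble - as.vector(Ale %*% lb))
  }
  ns <- nrow(A1)
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), ns)),
             cbind(A1, diag(ns)))
  b <- c(beq - as.vector(Aeq %*% lb), b1)
  cc <- c(if (sense == "max") obj else -obj, rep(0, ns))

  res <- simplex_two_phase(A, b, cc, tol = tol, max_iter = max_iter)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_))
  v <- res$x[seq_len(n)] + lb
  ## snap to bounds (simplex round-off)
  v <- pmin(pmax(v, lb), ub)
  list(status = "optimal", x = v, value = sum(obj * v))
}

## Standard-form core: max cc'x s.t. A x = b, x >= 0.
simplex_two_phase <- function(A, b, cc, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  iterate <- function(Tab, red, basis, ncols) {
    it <- 0L
    rhs_col <- ncol(Tab)
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex: iteration limit reached")
      cand <- which(red[seq_len(ncols)] > tol)
      if (!length(cand))
        return(list(Tab = Tab, red = red, basis = basis, unbounded = FALSE))
      pc <- cand[1L]                                  # Bland: lowest index enters
      col <- Tab[, pc]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(Tab = Tab, red = red, basis = basis, unbounded = TRUE))
      ratio <- Tab[pos, rhs_col] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + tol]
      pr <- tie[which.min(basis[tie])]                # Bland: lowest basis leaves
      piv <- Tab[pr, pc]
      Tab[pr, ] <- Tab[pr, ] / piv
      other <- seq_len(nrow(Tab))[-pr]
      if (length(other)) {
        fac <- Tab[other, pc]
        nz <- which(fac != 0)
        if (length(nz))
          Tab[other[nz], ] <- Tab[other[nz], , drop = FALSE] -
            outer(fac[nz], Tab[pr, ])
      }
      red <- red - red[pc] * Tab[pr, seq_along(red)]
      basis[pr] <- pc
    }
  }

  ## phase 1: artificial basis, minimise infeasibility
  nt <- n + m
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cz <- c(rep(0, n), rep(-1, m))
  red <- cz + colSums(Tab[, seq_len(nt), drop = FALSE])  # c - z with cB = -1
  r1 <- iterate(Tab, red, basis, nt)
  infeas <- sum(r1$Tab[r1$basis > n, nt + 1L])
  if (infeas > 1e-7) return(list(status = "infeasible"))
  Tab <- r1$Tab; basis <- r1$basis

  ## pivot residual artificials out, or drop redundant rows
  drop_rows <- integer(0)
  for (pr in which(basis > n)) {
    pc <- which(abs(Tab[pr, seq_len(n)]) > tol)
    if (length(pc)) {
      pc <- pc[1L]
      Tab[pr, ] <- Tab[pr, ] / Tab[pr, pc]
      other <- seq_len(nrow(Tab))[-pr]
      fac <- Tab[other, pc]
      nz <- which(fac != 0)
      if (length(nz))
        Tab[other[nz], ] <- Tab[other[nz], , drop = FALSE] -
          outer(fac[nz], Tab[pr, ])
      basis[pr] <- pc
    } else {
      drop_rows <- c(drop_rows, pr)
    }
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  ## phase 2 on the original columns
  Tab2 <- Tab[, c(seq_len(n), nt + 1L), drop = FALSE]
  red2 <- cc - as.vector(cc[basis] %*% Tab2[, seq_len(n), drop = FALSE])
  red2[basis] <- 0
  r2 <- iterate(Tab2, red2, basis, n)
  if (r2$unbounded) return(list(status = "unbounded"))
  x <- numeric(n)
  x[r2$basis] <- r2$Tab[, n + 1L]
  list(status = "optimal", x = x, value = sum(cc * x))
}
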