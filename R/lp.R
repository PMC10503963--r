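## Dense two-phase simplex for the small LPs that constraint-based analysis
## of toy-scale networks generates (tens to a few hundred variables). All
## FBA/FVA/Pareto/respirometry solves in the package go through solve_lp().

#' Solve a bounded-variable linear program
#'
#' Solves `max (or min) obj' x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le`, and `lb <= x <= ub`. Bounds may be infinite on either
#' side. Two backends are available: the package's own dense two-phase
#' simplex (`"simplex"`, the default) and `boot::simplex`
#' (`"boot"`), retained as an independent cross-check.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A_eq,b_eq equality constraints (matrix m x n, vector m); may be
#'   `NULL`/empty.
#' @param lb,ub variable bounds, length n.
#' @param A_le,b_le optional inequality constraints (`A_le x <= b_le`).
#' @param maximize logical; `FALSE` minimises.
#' @param backend `"simplex"` or `"boot"`.
#' @param tol feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and `x` (named after `obj` if it has names; present only
#'   when optimal).
#' @export
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, lb, ub,
                     A_le = NULL, b_le = NULL, maximize = TRUE,
                     backend = c("simplex", "boot"), tol = 1e-9) {
  backend <- match.arg(backend)
  n <- length(obj)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_le)) { A_le <- matrix(0, 0, n); b_le <- numeric(0) }
  A_eq <- as.matrix(A_eq); A_le <- as.matrix(A_le)
  stopifnot(length(lb) == n, length(ub) == n,
            ncol(A_eq) == n || nrow(A_eq) == 0,
            ncol(A_le) == n || nrow(A_le) == 0)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_))

  ## Transform to standard form: columns y >= 0.
  ## shift: x = lb + y       (finite lb)
  ## flip:  x = ub - y       (lb = -Inf, finite ub)
  ## split: x = y1 - y2      (both infinite)
  kind <- ifelse(is.finite(lb), "shift", ifelse(is.finite(ub), "flip",
                                                "split"))
  cols <- list(); ccost <- numeric(0); var_of <- integer(0)
  sign_of <- numeric(0); shift_x <- numeric(n)
  Aall <- rbind(A_eq, A_le)
  for (j in seq_len(n)) {
    if (kind[j] == "shift") {
      cols[[length(cols) + 1L]] <- Aall[, j]
      ccost <- c(ccost, obj[j]); var_of <- c(var_of, j)
      sign_of <- c(sign_of, 1); shift_x[j] <- lb[j]
    } else if (kind[j] == "flip") {
      cols[[length(cols) + 1L]] <- -Aall[, j]
      ccost <- c(ccost, -obj[j]); var_of <- c(var_of, j)
      sign_of <- c(sign_of, -1); shift_x[j] <- ub[j]
    } else {
      cols[[length(cols) + 1L]] <- Aall[, j]
      ccost <- c(ccost, obj[j]); var_of <- c(var_of, j)
      sign_of <- c(sign_of, 1)
      cols[[length(cols) + 1L]] <- -Aall[, j]
      ccost <- c(ccost, -obj[j]); var_of <- c(var_of, j)
      sign_of <- c(sign_of, -1)
      shift_x[j] <- 0
    }
  }
  ns <- length(cols)
  m1 <- nrow(A_eq); m2 <- nrow(A_le)
  Astr <- if (m1 + m2 > 0) do.call(cbind, cols) else
    matrix(0, 0, ns)
  rhs_adj <- as.vector(Aall %*% shift_x)
  b1 <- b_eq - rhs_adj[seq_len(m1)]
  b2 <- b_le - if (m2) rhs_adj[m1 + seq_len(m2)] else numeric(0)
  ## finite-span upper bounds on shifted/flipped columns
  span <- ifelse(sign_of > 0, ub[var_of] - shift_x[var_of],
                 shift_x[var_of] - lb[var_of])
  has_span <- is.finite(span)
  nspan <- sum(has_span)
  ## full standard-form system: rows = eq + le(+slack) + span(+slack)
  nslack <- m2 + nspan
  A <- matrix(0, m1 + m2 + nspan, ns + nslack)
  A[seq_len(m1 + m2), seq_len(ns)] <- Astr
  if (m2) A[m1 + seq_len(m2), ns + seq_len(m2)] <- diag(m2)
  if (nspan) {
    ii <- which(has_span)
    for (k in seq_len(nspan)) {
      A[m1 + m2 + k, ii[k]] <- 1
      A[m1 + m2 + k, ns + m2 + k] <- 1
    }
  }
  b <- c(b1, b2, if (nspan) span[has_span] else numeric(0))
  cost <- c(ccost, numeric(nslack))

  res <- if (backend == "simplex")
    simplex_standard(A, b, cost, maximize = maximize, tol = tol)
  else
    boot_structural(Astr, b1, b2, span, has_span, ccost,
                    maximize = maximize)

  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_))
  x <- shift_x
  for (k in seq_len(ns)) x[var_of[k]] <- x[var_of[k]] + sign_of[k] * res$y[k]
  names(x) <- names(obj)
  list(status = "optimal", objective = sum(obj * x), x = x)
}

## Two-phase tableau simplex: max cost'y s.t. A y = b, y >= 0. The
## phase-1 and phase-2 reduced-cost rows are carried inside the tableau and
## updated by the pivots, so each iteration is a single rank-1 update.
simplex_standard <- function(A, b, cost, maximize = TRUE, tol = 1e-9) {
  if (!maximize) {
    r <- simplex_standard(A, b, -cost, TRUE, tol)
    if (r$status == "optimal") r$objective <- -r$objective
    return(r)
  }
  m <- nrow(A); n <- ncol(A)
  if (m == 0) {
    if (any(cost > tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", y = numeric(n), objective = 0))
  }
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  ntot <- n + m
  ## rows 1..m constraints | row m+1 phase-1 reduced costs | m+2 phase-2
  Tm <- rbind(cbind(A, diag(m), b),
              c(-colSums(A), numeric(m), -sum(b)),
              c(-cost, numeric(m), 0))
  basis <- n + seq_len(m)

  do_pivot <- function(piv_r, piv_c) {
    prow <- Tm[piv_r, ] / Tm[piv_r, piv_c]
    Tm[piv_r, ] <<- prow
    fac <- Tm[, piv_c]
    fac[piv_r] <- 0
    Tm <<- Tm - tcrossprod(fac, prow)
    basis[piv_r] <<- piv_c
  }

  run <- function(obj_row, allowed) {
    it <- 0L
    maxit <- 200L + 60L * ntot
    bland_after <- 100L + 20L * ntot
    repeat {
      it <- it + 1L
      if (it > maxit) stop("simplex iteration limit exceeded")
      red <- Tm[obj_row, seq_len(ntot)]
      red[!allowed] <- Inf
      cand <- which(red < -tol)
      if (!length(cand)) return("optimal")
      enter <- if (it > bland_after) cand[1] else
        cand[which.min(red[cand])]
      col <- Tm[seq_len(m), enter]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- Tm[pos, ntot + 1] / col[pos]
      leave_set <- pos[ratio <= min(ratio) + tol]
      leave <- leave_set[which.min(basis[leave_set])]
      do_pivot(leave, enter)
    }
  }

  ## Phase 1: minimise artificial total (carried in row m+1)
  st <- run(m + 1L, allowed = rep(TRUE, ntot))
  if (st != "optimal") stop("phase 1 cannot be unbounded")
  if (-Tm[m + 1L, ntot + 1] > 1e-7) return(list(status = "infeasible"))
  ## pivot remaining zero-level artificials out, or drop redundant rows
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    piv_c <- which(abs(Tm[r, seq_len(n)]) > 1e-7)[1]
    if (is.na(piv_c)) { drop_rows <- c(drop_rows, r); next }
    do_pivot(r, piv_c)
  }
  if (length(drop_rows)) {
    Tm <- Tm[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
    m <- m - length(drop_rows)
  }
  allowed <- c(rep(TRUE, n), rep(FALSE, ntot - n))
  st <- run(m + 2L, allowed)
  if (st == "unbounded") return(list(status = "unbounded"))
  y <- numeric(n)
  struct <- basis <= n
  y[basis[struct]] <- Tm[seq_len(m), ntot + 1][struct]
  y[y < 0 & y > -1e-9] <- 0
  list(status = "optimal", y = y, objective = sum(cost * y))
}

## boot::simplex backend on the shifted structural form (independent
## cross-check): equalities as A3, finite spans and <= rows as A1/A2.
boot_structural <- function(Astr, b_eq, b_le, span, has_span, cost,
                            maximize = TRUE) {
  if (!requireNamespace("boot", quietly = TRUE))
    stop("backend 'boot' requires the boot package")
  ns <- ncol(Astr)
  m1 <- length(b_eq); m2 <- length(b_le)
  A3 <- if (m1) Astr[seq_len(m1), , drop = FALSE] else NULL
  b3 <- b_eq
  if (m1) {
    flip <- b3 < 0
    A3[flip, ] <- -A3[flip, , drop = FALSE]
    b3[flip] <- -b3[flip]
  }
  le_A <- rbind(if (m2) Astr[m1 + seq_len(m2), , drop = FALSE],
                if (any(has_span)) diag(ns)[has_span, , drop = FALSE])
  le_b <- c(b_le, span[has_span])
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  if (!is.null(le_A)) {
    neg <- le_b < 0
    if (any(!neg)) { A1 <- le_A[!neg, , drop = FALSE]; b1 <- le_b[!neg] }
    if (any(neg)) { A2 <- -le_A[neg, , drop = FALSE]; b2 <- -le_b[neg] }
  }
  out <- tryCatch(
    boot::simplex(a = cost, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = maximize,
                  n.iter = 200 + 20 * (m1 + length(le_b) + ns),
                  eps = 1e-10),
    error = function(e) NULL)
  if (is.null(out) || out$solved != 1) return(list(status = "infeasible"))
  list(status = "optimal", y = as.numeric(out$soln),
       objective = out$value)
}
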