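#' Solve a linear program with equality constraints and variable bounds
#'
#' Solves `min/max obj' x` subject to `A x = b` and `lb <= x <= ub`.
#' This is the computational form every flux balance problem in the package
#' reduces to (inequalities are modelled by slack variables with one-sided
#' bounds before calling).
#'
#' The default backend is a dense bounded-variable two-phase primal simplex
#' implemented here. Alternative backends (`"boot"`, `"pracma"`) route the
#' same problem through [boot::simplex()] or `pracma::linprog()` after
#' shifting variables to the non-negative orthant; they exist as independent
#' cross-checks of the default backend on well-behaved problems.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A dense or [Matrix::Matrix()] constraint matrix, `m x n`.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; must be finite.
#' @param maximize if `TRUE` maximize `obj' x`, otherwise minimize.
#' @param backend `"dense"` (default), `"boot"` or `"pracma"`.
#' @param tol numerical tolerance on reduced costs and feasibility.
#' @param max_iter simplex iteration cap.
#' @return list with `x` (solution, length `n`), `objective`, and `status`
#'   (`"optimal"`, `"infeasible"` or `"iteration_limit"`).
#' @export
solve_lp <- function(obj, A, b, lb, ub,
                     maximize = FALSE,
                     backend = c("dense", "boot", "pracma"),
                     tol = 1e-9, max_iter = 10000L) {
  backend <- match.arg(backend)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  switch(backend,
    dense  = lp_simplex_dense(obj, A, b, lb, ub, maximize, tol, max_iter),
    boot   = lp_backend_boot(obj, A, b, lb, ub, maximize),
    pracma = lp_backend_pracma(obj, A, b, lb, ub, maximize)
  )
}

# Bounded-variable two-phase primal simplex, dense arithmetic.
# Variables 1..n are structural, n+1..n+m are phase-1 artificials.
# Nonbasic variables rest at one of their bounds; the basis inverse is
# maintained by eta updates and refactorized periodically for stability.
# Dantzig pricing with a switch to Bland's rule after a run of degenerate
# pivots guards against cycling.
lp_simplex_dense <- function(obj, A, b, lb, ub, maximize, tol, max_iter) {
  n <- ncol(A)
  m <- nrow(A)
  cc <- if (maximize) -obj else obj

  # start nonbasic structurals at the bound closer to zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  r <- b - as.vector(A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  x <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))

  basis <- n + seq_len(m)
  Binv <- diag(sg, nrow = m) # inverse of diag(sg) is itself
  phase <- 1L
  cost <- c(rep(0, n), rep(1, m))
  degen_run <- 0L
  it <- 0L

  recompute_xb <- function() {
    nb <- setdiff(seq_len(n + m), basis)
    as.vector(Binv %*% (b - Afull[, nb, drop = FALSE] %*% x[nb]))
  }
  x[basis] <- recompute_xb()

  while (it < max_iter) {
    it <- it + 1L
    if (it %% 200L == 0L) { # periodic refactorization
      Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                       error = function(e) Binv)
      x[basis] <- recompute_xb()
    }
    nb <- setdiff(seq_len(n + m), basis)
    if (phase == 2L) nb <- nb[nb <= n] # artificials may not re-enter
    y <- as.vector(crossprod(Binv, cost[basis]))
    d <- cost[nb] - as.vector(crossprod(Afull[, nb, drop = FALSE], y))

    elig <- which((!at_upper[nb] & d < -tol) | (at_upper[nb] & d > tol))
    if (length(elig) == 0L) {
      # optimal for the current phase
      if (phase == 1L) {
        if (sum(cost * x) > 1e-7)
          return(list(x = rep(NA_real_, n), objective = NA_real_,
                      status = "infeasible"))
        # pin artificials to zero and switch to the real objective
        arts <- n + seq_len(m)
        ubf[arts] <- 0
        idle <- setdiff(arts, basis)
        x[idle] <- 0
        at_upper[idle] <- FALSE
        cost <- c(cc, rep(0, m))
        phase <- 2L
        degen_run <- 0L
        next
      }
      xs <- x[seq_len(n)]
      return(list(x = xs, objective = sum(obj * xs), status = "optimal"))
    }
    e_loc <- if (degen_run > 60L) elig[which.min(nb[elig])] # Bland's rule
             else elig[which.max(abs(d[elig]))]
    e <- nb[e_loc]
    delta <- if (at_upper[e]) -1 else 1
    alpha <- as.vector(Binv %*% Afull[, e])
    dxb <- -alpha * delta

    # ratio test: basic variables hitting a bound, or the entering variable
    # flipping to its opposite bound
    ts <- rep(Inf, m)
    hit_upper <- rep(FALSE, m)
    dec <- dxb < -tol
    inc <- dxb > tol
    if (any(dec)) ts[dec] <- (x[basis[dec]] - lbf[basis[dec]]) / (-dxb[dec])
    if (any(inc)) {
      ts[inc] <- (ubf[basis[inc]] - x[basis[inc]]) / dxb[inc]
      hit_upper[inc] <- TRUE
    }
    ts[ts < 0] <- 0
    t_basic <- suppressWarnings(min(ts))
    t_flip <- ubf[e] - lbf[e]
    tmax <- min(t_basic, t_flip)
    if (!is.finite(tmax))
      return(list(x = rep(NA_real_, n),
                  objective = if (maximize) Inf else -Inf,
                  status = "unbounded"))
    degen_run <- if (tmax < tol) degen_run + 1L else 0L

    x[basis] <- x[basis] + dxb * tmax
    x[e] <- x[e] + delta * tmax

    if (t_flip <= t_basic) { # bound flip, basis unchanged
      at_upper[e] <- !at_upper[e]
      next
    }
    cand <- which(ts <= tmax + tol)
    leave <- cand[which.min(basis[cand])] # ties: lowest variable index
    lv <- basis[leave]
    x[lv] <- if (hit_upper[leave]) ubf[lv] else lbf[lv]
    at_upper[lv] <- hit_upper[leave]
    at_upper[e] <- FALSE
    basis[leave] <- e
    # eta update of Binv
    piv <- alpha[leave]
    Binv[leave, ] <- Binv[leave, ] / piv
    adj <- which(abs(alpha) > 0 & seq_len(m) != leave)
    if (length(adj))
      Binv[adj, ] <- Binv[adj, , drop = FALSE] -
        outer(alpha[adj], Binv[leave, ])
  }
  list(x = rep(NA_real_, n), objective = NA_real_, status = "iteration_limit")
}

# Cross-check backend: boot::simplex on the shifted problem x = v - lb >= 0.
lp_backend_boot <- function(obj, A, b, lb, ub, maximize) {
  if (!requireNamespace("boot", quietly = TRUE))
    stop("backend 'boot' requires the boot package")
  n <- ncol(A)
  beq <- b - as.vector(A %*% lb)
  flip <- beq < 0
  A3 <- A
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  beq[flip] <- -beq[flip]
  res <- boot::simplex(a = obj, A1 = diag(n), b1 = ub - lb,
                       A3 = A3, b3 = beq, maxi = maximize,
                       n.iter = 5000)
  if (res$solved != 1)
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  v <- as.vector(res$soln) + lb
  list(x = v, objective = sum(obj * v), status = "optimal")
}

# Cross-check backend: pracma::linprog on the shifted problem.
lp_backend_pracma <- function(obj, A, b, lb, ub, maximize) {
  if (!requireNamespace("pracma", quietly = TRUE))
    stop("backend 'pracma' requires the pracma package")
  n <- ncol(A)
  cc <- if (maximize) -obj else obj
  beq <- b - as.vector(A %*% lb)
  res <- tryCatch(
    pracma::linprog(cc, A = diag(n), b = ub - lb, Aeq = A, beq = beq,
                    maxiter = 5000),
    error = function(e) NULL)
  if (is.null(res) || res$errno != 1)
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  v <- as.vector(res$x) + lb
  list(x = v, objective = sum(obj * v), status = "optimal")
}
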