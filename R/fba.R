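# FBA, parsimonious FBA and flux variability analysis for one constrained
# cell. All three reduce to solve_lp() on the steady-state polytope
# {v : S v = 0, lb <= v <= ub}, with per-cell capacity overrides merged into
# the default bounds.

# merge protein-capacity overrides into the model's default bounds.
# Overrides tighten the upper bound; for reversible reactions the capacity
# applies symmetrically (lb raised to -vmax) unless upper_only.
merge_overrides <- function(model, overrides, upper_only = FALSE) {
  lb <- model$lb
  ub <- model$ub
  if (!is.null(overrides) && nrow(overrides)) {
    if (!all(overrides$reaction %in% model$reactions))
      stop("override for unknown reaction(s): ",
           paste(setdiff(overrides$reaction, model$reactions), collapse = ", "))
    r <- overrides$reaction
    ub[r] <- pmin(ub[r], overrides$vmax)
    if (!upper_only)
      lb[r] <- pmax(lb[r], -overrides$vmax)
    lb[r] <- pmin(lb[r], ub[r]) # keep lb <= ub when vmax < a positive lb
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximizes the biomass flux subject to steady-state mass balance and flux
#' bounds (the model's defaults merged with per-cell capacity overrides).
#'
#' @param model a [metabolic_model()].
#' @param overrides optional `cell_constraints` from [build_cell_bounds()].
#' @param upper_only apply capacity overrides to upper bounds only.
#' @param backend LP backend, see [solve_lp()].
#' @return a `flux_solution`: list with `fluxes` (named vector), `growth`
#'   (biomass flux, 0 when infeasible), `status`, `total_flux` (sum |v|).
#' @export
fba <- function(model, overrides = NULL, upper_only = FALSE,
                backend = "dense") {
  bb <- merge_overrides(model, overrides, upper_only)
  obj <- as.numeric(model$reactions == model$biomass)
  sol <- solve_lp(obj, model$S, rep(0, length(model$metabolites)),
                  bb$lb, bb$ub, maximize = TRUE, backend = backend)
  flux_solution(model, sol)
}

flux_solution <- function(model, sol) {
  if (sol$status != "optimal") {
    return(structure(list(fluxes = stats::setNames(
      rep(NA_real_, length(model$reactions)), model$reactions),
      growth = 0, status = sol$status, total_flux = NA_real_),
      class = "flux_solution"))
  }
  v <- stats::setNames(sol$x, model$reactions)
  structure(list(fluxes = v, growth = unname(v[model$biomass]),
                 status = "optimal", total_flux = sum(abs(v))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux solution: status %s, growth %.6g/hr, total |v| %.6g\n",
              x$status, x$growth, x$total_flux))
  invisible(x)
}

# build the split-variable LP used by pFBA and pinned FVA:
# v = v+ - v-, v+,v- >= 0, minimizing sum(v+ + v-) selects the flux vector
# with least total absolute flux. Optional extra rows: growth pin
# (biomass >= frac * mu*, via a bounded slack) and total-flux pin.
split_lp_parts <- function(model, lb, ub) {
  n <- length(model$reactions)
  S <- as.matrix(model$S)
  A <- cbind(S, -S)
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  list(A = A, lo = lo, hi = hi, n = n)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the optimal growth rate, then -- holding biomass at or
#' above `optimality_fraction` times that optimum -- the flux vector of
#' minimum total absolute flux, found by splitting every reaction into
#' non-negative forward and backward parts and minimizing their sum.
#'
#' @inheritParams fba
#' @param optimality_fraction fraction of optimal growth retained in stage 2.
#' @return a `flux_solution` (with `total_flux` the minimized sum of
#'   absolute fluxes).
#' @export
pfba <- function(model, overrides = NULL, optimality_fraction = 1.0,
                 upper_only = FALSE, backend = "dense") {
  s1 <- fba(model, overrides, upper_only, backend)
  if (s1$status != "optimal") return(s1)
  bb <- merge_overrides(model, overrides, upper_only)
  parts <- split_lp_parts(model, bb$lb, bb$ub)
  n <- parts$n
  mu_pin <- optimality_fraction * s1$growth - 1e-9
  # growth pin: v_bio - slack = mu_pin, slack in [0, Inf)
  bio <- as.numeric(model$reactions == model$biomass)
  pin_row <- c(bio, -bio, -1)
  A <- rbind(cbind(parts$A, 0), pin_row)
  b <- c(rep(0, length(model$metabolites)), mu_pin)
  lo <- c(parts$lo, 0)
  hi <- c(parts$hi, 1e7)
  obj <- c(rep(1, 2 * n), 0)
  sol <- solve_lp(obj, A, b, lo, hi, maximize = FALSE, backend = backend)
  if (sol$status != "optimal") return(flux_solution(model, sol))
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  flux_solution(model, list(x = v, status = "optimal"))
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to biomass at or above
#' `optimality_fraction` of the FBA optimum and, optionally, total absolute
#' flux held at the parsimonious total (plus a small slack).
#'
#' @inheritParams pfba
#' @param reactions reactions to scan; defaults to all.
#' @param pin_total_flux if `TRUE`, additionally require
#'   `sum |v| <= pFBA total + pin_slack`.
#' @param pin_slack absolute slack on the total-flux pin.
#' @return data frame `reaction`, `min`, `max`.
#' @export
fva <- function(model, overrides = NULL, optimality_fraction = 1.0,
                reactions = NULL, pin_total_flux = FALSE, pin_slack = 1e-6,
                upper_only = FALSE, backend = "dense") {
  s1 <- fba(model, overrides, upper_only, backend)
  if (s1$status != "optimal") stop("FVA: model infeasible")
  if (is.null(reactions)) reactions <- model$reactions
  bb <- merge_overrides(model, overrides, upper_only)
  parts <- split_lp_parts(model, bb$lb, bb$ub)
  n <- parts$n
  bio <- as.numeric(model$reactions == model$biomass)
  A <- rbind(cbind(parts$A, 0), c(bio, -bio, -1))
  b <- c(rep(0, length(model$metabolites)),
         optimality_fraction * s1$growth - 1e-9)
  lo <- c(parts$lo, 0)
  hi <- c(parts$hi, 1e7)
  if (pin_total_flux) {
    ps <- pfba(model, overrides, optimality_fraction, upper_only, backend)
    if (ps$status != "optimal") stop("FVA: pFBA stage infeasible")
    # sum(v+ + v-) + slack2 = total + pin_slack, slack2 >= 0
    A <- rbind(cbind(A, 0), c(rep(1, 2 * n), 0, 1))
    b <- c(b, ps$total_flux + pin_slack)
    lo <- c(lo, 0)
    hi <- c(hi, 1e7)
  }
  nv <- ncol(A)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$reactions)
    obj <- numeric(nv)
    obj[j] <- 1
    obj[n + j] <- -1
    lo_ <- solve_lp(obj, A, b, lo, hi, maximize = FALSE, backend = backend)
    hi_ <- solve_lp(obj, A, b, lo, hi, maximize = TRUE, backend = backend)
    if (lo_$status == "optimal") out$min[k] <- lo_$objective
    if (hi_$status == "optimal") out$max[k] <- hi_$objective
  }
  out
}

#' Reactions whose flux sits at their protein-derived capacity bound
#'
#' @param sol an optimal `flux_solution`.
#' @param overrides the `cell_constraints` used to produce it.
#' @param tol relative tolerance for "at the bound".
#' @param default_bound overrides at or above this are not real constraints.
#' @return character vector of reaction ids.
#' @export
active_bounds <- function(sol, overrides, tol = 1e-6, default_bound = 1000) {
  if (sol$status != "optimal") stop("active_bounds needs an optimal solution")
  if (is.null(overrides) || !nrow(overrides)) return(character())
  keep <- overrides$vmax < default_bound
  r <- overrides$reaction[keep]
  vm <- overrides$vmax[keep]
  r[abs(sol$fluxes[r]) >= (1 - tol) * vm]
}
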