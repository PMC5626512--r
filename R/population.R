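# Whole-population simulation and the analytics used to characterize
# metabolic heterogeneity: growth-rate histograms, growth-normalized flux
# PCA, comparison to reference fluxes, and bound-uptake bimodality.

#' Simulate a population of constrained cells
#'
#' For each row of the count matrix: build that cell's capacity bounds,
#' solve parsimonious FBA, and record growth rate and fluxes. Infeasible
#' cells are flagged (growth recorded as 0), never silently dropped.
#'
#' @param model a [metabolic_model()] (apply the medium and knockouts first
#'   via [apply_medium_and_knockouts()], or pass `medium`/`knockouts` here).
#' @param samples `cells x proteins` count matrix from [sample_population()].
#' @param kcats a [kcat_table()].
#' @param medium optional named uptake-magnitude vector.
#' @param knockouts optional gene list.
#' @param units constants from [unit_constants()].
#' @param optimality_fraction passed to [pfba()].
#' @param default_bound the "unconstrained" bound.
#' @return a `population_result`: list with `growth` (per cell, /hr),
#'   `fluxes` (cells x reactions), `counts`, `feasible` (logical),
#'   `active` (list of per-cell active protein-bound reaction sets),
#'   `model`, `seed`.
#' @export
simulate_population <- function(model, samples, kcats, medium = NULL,
                                knockouts = NULL, units = unit_constants(),
                                optimality_fraction = 1.0,
                                default_bound = 1000) {
  if (!is.null(medium) || !is.null(knockouts))
    model <- apply_medium_and_knockouts(
      model, medium, if (is.null(knockouts)) character() else knockouts)
  n <- nrow(samples)
  growth <- numeric(n)
  feasible <- logical(n)
  fluxes <- matrix(NA_real_, n, length(model$reactions),
                   dimnames = list(NULL, model$reactions))
  active <- vector("list", n)
  for (i in seq_len(n)) {
    ov <- build_cell_bounds(model, samples[i, ], kcats, units, default_bound)
    sol <- pfba(model, ov, optimality_fraction)
    if (sol$status == "optimal") {
      growth[i] <- sol$growth
      feasible[i] <- TRUE
      fluxes[i, ] <- sol$fluxes
      active[[i]] <- active_bounds(sol, ov, default_bound = default_bound)
    } else {
      growth[i] <- 0
      feasible[i] <- FALSE
      active[[i]] <- character()
    }
  }
  if (any(!feasible))
    message(sum(!feasible), " of ", n, " cells infeasible")
  structure(list(growth = growth, fluxes = fluxes, counts = samples,
                 feasible = feasible, active = active, model = model,
                 seed = attr(samples, "seed")),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  mu <- x$growth[x$feasible]
  cat(sprintf("population: %d cells (%d feasible), mean growth %.4g/hr, range [%.4g, %.4g]\n",
              length(x$growth), sum(x$feasible), mean(mu),
              min(mu), max(mu)))
  invisible(x)
}

#' Growth-rate histogram
#'
#' Density-normalized histogram of per-cell growth rates over a fixed range
#' (the integral over the bins is 1).
#'
#' @param result a `population_result` (or a numeric vector of growth rates).
#' @param nbins number of bins.
#' @param range histogram range (/hr).
#' @param include_infeasible include infeasible cells at growth 0.
#' @return list with `breaks`, `mids`, `density`, `counts`, `n`.
#' @export
growth_histogram <- function(result, nbins = 50, range = c(0, 0.7),
                             include_infeasible = FALSE) {
  mu <- if (is.numeric(result)) result
        else if (include_infeasible) result$growth
        else result$growth[result$feasible]
  if (!length(mu)) stop("no feasible cells to bin")
  mu <- pmin(pmax(mu, range[1]), range[2]) # clamp into the fixed range
  breaks <- seq(range[1], range[2], length.out = nbins + 1)
  counts <- tabulate(findInterval(mu, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  width <- diff(breaks)[1]
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(nbins + 1)]) / 2,
       density = counts / (sum(counts) * width), counts = counts,
       n = length(mu))
}

#' Principal component analysis of growth-normalized fluxes
#'
#' Samples cells at random, divides each cell's flux vector by its growth
#' rate (isolating growth-independent differences in pathway usage), drops
#' zero-variance reactions, and runs a covariance PCA (no per-reaction
#' rescaling, no rotation).
#'
#' @param result a `population_result`.
#' @param n_cells number of cells entering the PCA.
#' @param seed seed for the cell subsample.
#' @param min_growth cells at or below this growth are excluded before
#'   normalization.
#' @return list with `loadings`, `explained_variance` (fractions,
#'   non-increasing), `scores`, `reactions`, `cells`.
#' @export
flux_pca <- function(result, n_cells = 1000, seed = 1L, min_growth = 1e-9) {
  ok <- which(result$feasible & result$growth > min_growth)
  if (length(ok) < 2) stop("not enough growing cells for PCA")
  n_cells <- min(n_cells, length(ok))
  with_local_seed(seed, {
    pick <- sample(ok, n_cells)
  })
  V <- result$fluxes[pick, , drop = FALSE] / result$growth[pick]
  keep <- apply(V, 2, stats::sd) > 0
  V <- V[, keep, drop = FALSE]
  p <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(loadings = p$rotation, explained_variance = ev, scores = p$x,
       reactions = colnames(V), cells = pick)
}

#' Compare population mean fluxes with reference fluxes
#'
#' @param result a `population_result`.
#' @param reference named numeric vector: reaction id -> reference flux.
#' @return list with `means` (population mean flux per referenced reaction),
#'   `reference`, and `rmsd` (root mean squared difference).
#' @export
compare_fluxes <- function(result, reference) {
  missing_rx <- setdiff(names(reference), colnames(result$fluxes))
  if (length(missing_rx))
    stop("reference reaction(s) not in model: ",
         paste(missing_rx, collapse = ", "))
  fx <- result$fluxes[result$feasible, names(reference), drop = FALSE]
  means <- colMeans(fx)
  list(means = means, reference = reference,
       rmsd = sqrt(mean((means - reference)^2)))
}

#' Fraction of cells at the uptake bound of an exchange reaction
#'
#' Classifies cells as taking the substrate up at its maximum allowable
#' rate, at a basal rate, or in between, and flags bimodality when both
#' extreme classes are populated and the middle is nearly empty.
#'
#' @param result a `population_result`.
#' @param exchange exchange reaction id.
#' @param medium the medium the population was simulated on.
#' @param tol relative tolerance for "at the maximum".
#' @param basal_fraction uptakes at or below this fraction of the maximum
#'   count as basal.
#' @param middle_max bimodality requires the middle fraction at or below
#'   this.
#' @param min_mode bimodality requires both extreme fractions at or above
#'   this.
#' @return list with `at_max`, `basal`, `middle` (fractions over feasible
#'   cells) and `bimodal` (flag).
#' @export
bound_uptake_fraction <- function(result, exchange, medium, tol = 0.01,
                                  basal_fraction = 0.1, middle_max = 0.1,
                                  min_mode = 0.05) {
  if (!exchange %in% names(medium))
    stop("exchange '", exchange, "' not in the medium")
  cap <- medium[[exchange]]
  uptake <- -result$fluxes[result$feasible, exchange]
  at_max <- mean(uptake >= (1 - tol) * cap)
  basal <- mean(uptake <= basal_fraction * cap)
  middle <- 1 - at_max - basal
  list(at_max = at_max, basal = basal, middle = middle,
       bimodal = at_max >= min_mode && basal >= min_mode &&
         middle <= middle_max)
}
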