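# Repair of overly-constraining turnover numbers. Curated kcat databases
# mix organisms, mutants and assay conditions, and a single low value can
# throttle an entire simulated population. Two complementary strategies:
# an iterative doubling of the most frequently growth-limiting capacity
# until a target mean growth rate is reached, and a micro genetic algorithm
# that selects which kcats to lift outright so the simulated growth-rate
# distribution matches an observed one.

#' Harmonize turnover numbers within protein complexes
#'
#' Within every AND-group of a GPR (a protein complex), all member kcats are
#' raised to the group maximum, applied transitively until a fixed point
#' (a gene in two complexes propagates the larger maximum to both).
#'
#' @param kcats a [kcat_table()].
#' @param model a [metabolic_model()] supplying the GPRs.
#' @return the harmonized [kcat_table()].
#' @export
harmonize_complex_kcats <- function(kcats, model) {
  groups <- unique(unlist(lapply(model$gpr_tree, gpr_and_groups),
                          recursive = FALSE))
  if (!length(groups)) return(kcats)
  repeat {
    changed <- FALSE
    for (g in groups) {
      members <- match(g, kcats$gene)
      members <- members[!is.na(members)]
      if (length(members) < 2) next
      mx <- max(kcats$kcat[members])
      low <- members[kcats$kcat[members] < mx]
      if (length(low)) {
        kcats$kcat[low] <- mx
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  kcats
}

#' Iterative capacity doubling toward a target mean growth rate
#'
#' Repeatedly: sample a fresh batch of cells, solve parsimonious FBA for
#' each, tally which reaction sits at its protein-derived capacity bound
#' most often, and double the turnover number(s) behind that reaction --
#' the most abundant isozyme for OR rules, every subunit for AND complexes.
#' Stops as soon as a batch's mean growth rate reaches the target.
#'
#' Each iteration draws its batch with seed `seed + iteration`, so the
#' stopping rule is never fit to a single fixed population. Ties in the
#' activity tally break toward the lexicographically smallest reaction id.
#'
#' @param model a [metabolic_model()] with medium already applied (or pass
#'   `medium`).
#' @param marginals,corr,cal sampling inputs, see [sample_population()].
#' @param kcats starting [kcat_table()].
#' @param medium optional named uptake-magnitude vector.
#' @param target_mean_growth target batch mean growth rate (/hr), > 0.
#' @param batch_size cells per iteration.
#' @param seed base seed.
#' @param max_iter iteration cap.
#' @param units constants from [unit_constants()].
#' @return list with `kcats` (updated table, provenance `doubled xN`) and
#'   `log` (data frame: `iteration`, `reaction`, `gene`, `old_kcat`,
#'   `new_kcat`, `batch_mean_growth`).
#' @export
doubling_procedure <- function(model, marginals, corr = NULL, cal, kcats,
                               medium = NULL,
                               target_mean_growth, batch_size = 400,
                               seed = 1L, max_iter = 100L,
                               units = unit_constants()) {
  if (target_mean_growth <= 0) stop("target_mean_growth must be positive")
  if (!is.null(medium))
    model <- apply_medium_and_knockouts(model, medium)
  mean_counts <- stats::setNames(marginals$shape * marginals$scale,
                                 marginals$protein_id)
  log_rows <- list()
  for (iter in seq_len(max_iter)) {
    samples <- sample_population(batch_size, marginals, corr, cal,
                                 seed = seed + iter)
    pop <- suppressMessages(
      simulate_population(model, samples, kcats, units = units))
    mu_bar <- mean(pop$growth)
    if (mu_bar >= target_mean_growth) {
      lg <- if (length(log_rows)) do.call(rbind, log_rows)
            else data.frame(iteration = integer(), reaction = character(),
                            gene = character(), old_kcat = numeric(),
                            new_kcat = numeric(),
                            batch_mean_growth = numeric(),
                            stringsAsFactors = FALSE)
      return(list(kcats = kcats, log = lg))
    }
    tally <- table(unlist(pop$active))
    if (!length(tally))
      stop("growth limited by medium, not proteins: mean growth ",
           signif(mu_bar, 4), " below target with no active protein bound")
    best <- sort(names(tally)[tally == max(tally)])[1]
    genes <- gpr_doubling_genes(model$gpr_tree[[best]], mean_counts)
    hit <- match(genes, kcats$gene)
    if (anyNA(hit)) {
      # genes relying on the default kcat get a table row before doubling
      add <- genes[is.na(hit)]
      dflt <- attr(kcats, "default_kcat")
      kcats <- rbind(kcats, data.frame(gene = add, kcat = dflt,
                                       provenance = "default",
                                       stringsAsFactors = FALSE))
      class(kcats) <- c("kcat_table", "data.frame")
      attr(kcats, "default_kcat") <- dflt
      hit <- match(genes, kcats$gene)
    }
    old <- kcats$kcat[hit]
    kcats$kcat[hit] <- 2 * old
    nd <- ifelse(grepl("^doubled x", kcats$provenance[hit]),
                 as.integer(sub("^doubled x", "", kcats$provenance[hit])) + 1L,
                 1L)
    kcats$provenance[hit] <- paste0("doubled x", nd)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      iteration = iter, reaction = best, gene = genes, old_kcat = old,
      new_kcat = 2 * old, batch_mean_growth = mu_bar,
      stringsAsFactors = FALSE)
  }
  cond <- simpleError(paste0("doubling did not reach target mean growth ",
                             target_mean_growth, " within ", max_iter,
                             " iterations"))
  cond$log <- do.call(rbind, log_rows)
  stop(cond)
}

#' Replay a doubling log onto a kcat table
#'
#' Applies the logged doubling events in order; replaying the log of
#' [doubling_procedure()] onto its starting table reproduces its final
#' table exactly.
#'
#' @param kcats the starting [kcat_table()].
#' @param log the doubling log.
#' @return the updated [kcat_table()].
#' @export
replay_doubling_log <- function(kcats, log) {
  for (i in seq_len(nrow(log))) {
    j <- match(log$gene[i], kcats$gene)
    if (is.na(j)) {
      kcats <- rbind(kcats, data.frame(gene = log$gene[i],
                                       kcat = log$new_kcat[i],
                                       provenance = "doubled x1",
                                       stringsAsFactors = FALSE))
    } else {
      kcats$kcat[j] <- 2 * kcats$kcat[j]
    }
  }
  kcats
}

#' Micro-GA configuration
#'
#' @param pop_size number of genomes per generation (at least 5).
#' @param cells cells simulated per fitness evaluation.
#' @param bins,range growth-rate histogram binning for the fit statistic.
#' @param max_generations generation cap.
#' @param restart_similarity mean bitwise similarity to the elite that
#'   triggers a population restart around the elite.
#' @param seed base seed.
#' @param stop_fitness optional early-stop threshold on the elite fitness.
#' @export
ga_config <- function(pop_size = 10L, cells = 50L, bins = 50L,
                      range = c(0, 0.7), max_generations = 200L,
                      restart_similarity = 0.95, seed = 1L,
                      stop_fitness = NULL) {
  if (pop_size < 5) stop("micro-GA population must be at least 5")
  if (bins < 10) stop("use at least 10 histogram bins")
  structure(list(pop_size = as.integer(pop_size), cells = as.integer(cells),
                 bins = as.integer(bins), range = range,
                 max_generations = as.integer(max_generations),
                 restart_similarity = restart_similarity,
                 seed = as.integer(seed), stop_fitness = stop_fitness),
            class = "ga_config")
}

#' Simulation context shared by the relaxation search
#'
#' @param model a [metabolic_model()] with medium applied (or `medium` set).
#' @param marginals,corr,cal sampling inputs.
#' @param kcats curated [kcat_table()].
#' @param candidates genes whose kcat the search may lift; defaults to all
#'   genes in `kcats`.
#' @param medium optional named uptake-magnitude vector.
#' @param lift_kcat the value a lifted gene's kcat is set to (1/s).
#' @param units constants from [unit_constants()].
#' @export
ga_context <- function(model, marginals, corr = NULL, cal, kcats,
                       candidates = NULL, medium = NULL, lift_kcat = 38000,
                       units = unit_constants()) {
  if (!is.null(medium))
    model <- apply_medium_and_knockouts(model, medium)
  if (is.null(candidates)) candidates <- kcats$gene
  list(model = model, marginals = marginals, corr = corr, cal = cal,
       kcats = kcats, candidates = candidates, lift_kcat = lift_kcat,
       units = units)
}

# apply a genome's lift pattern to the curated kcat table
apply_genome <- function(genome, context) {
  kc <- context$kcats
  lift <- context$candidates[genome == 1L]
  j <- match(lift, kc$gene)
  kc$kcat[j[!is.na(j)]] <- context$lift_kcat
  kc$provenance[j[!is.na(j)]] <- "lifted-38000"
  kc
}

#' Fitness of one kcat-selection genome
#'
#' Applies the genome (bit 1 = lift that candidate's kcat), simulates a
#' small population, bins growth rates like the target histogram, and
#' scores `-sum((p - q)^2)` over the normalized bin proportions (higher is
#' better, 0 is a perfect match). Deterministic given the seed. An
#' all-infeasible population scores `-Inf`.
#'
#' @param genome integer/logical bit vector over `context$candidates`.
#' @param context from [ga_context()].
#' @param target_hist normalized target histogram (proportions summing
#'   to 1) over `cfg$bins` bins on `cfg$range`.
#' @param cfg a [ga_config()].
#' @param seed seed for the evaluation population (defaults to
#'   `cfg$seed`).
#' @export
genome_fitness <- function(genome, context, target_hist, cfg, seed = NULL) {
  stopifnot(length(genome) == length(context$candidates))
  if (abs(sum(target_hist) - 1) > 1e-6)
    stop("target histogram must be normalized to sum 1")
  if (is.null(seed)) seed <- cfg$seed
  kc <- apply_genome(genome, context)
  samples <- sample_population(cfg$cells, context$marginals, context$corr,
                               context$cal, seed = seed)
  pop <- suppressMessages(
    simulate_population(context$model, samples, kc, units = context$units))
  if (!any(pop$feasible)) return(-Inf)
  h <- growth_histogram(pop, nbins = cfg$bins, range = cfg$range)
  p <- h$counts / sum(h$counts)
  -sum((p - target_hist)^2)
}

#' Bin a growth-rate vector into a normalized target histogram
#'
#' @param mu growth rates (/hr).
#' @param cfg a [ga_config()] supplying bins and range.
#' @return bin proportions summing to 1.
#' @export
target_histogram <- function(mu, cfg) {
  h <- growth_histogram(mu, nbins = cfg$bins, range = cfg$range)
  h$counts / sum(h$counts)
}

#' Micro genetic algorithm for turnover-number selection
#'
#' Small-population GA with elitism and no mutation: each generation keeps
#' the best genome unchanged, fills the rest by uniform crossover of
#' parents chosen by binary tournament (selection biased by fitness), and
#' -- when the population has converged onto the elite (mean bitwise
#' similarity at or above `cfg$restart_similarity`) -- restarts around the
#' elite by re-randomizing everyone else. Fitness evaluations are memoized
#' per bit pattern, and every generation is evaluated on the same seeded
#' population so genomes are compared on equal footing.
#'
#' @param context from [ga_context()].
#' @param target_hist normalized target histogram (see
#'   [target_histogram()]).
#' @param cfg a [ga_config()].
#' @return list with `best` (bit vector), `best_fitness`, `trace` (data
#'   frame per generation: elite fitness, mean fitness, restarts so far),
#'   `population` (final bit matrix), `hit_cap` (TRUE when the generation
#'   cap ended the search).
#' @export
microga_select <- function(context, target_hist, cfg = ga_config()) {
  nb <- length(context$candidates)
  cache <- new.env(parent = emptyenv())
  evalg <- function(g) {
    key <- paste(g, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- genome_fitness(g, context, target_hist, cfg)
    cache[[key]] <- f
    f
  }
  with_local_seed(cfg$seed, {
    pop <- matrix(stats::rbinom(cfg$pop_size * nb, 1L, 0.5),
                  cfg$pop_size, nb)
    fit <- apply(pop, 1, evalg)
    restarts <- 0L
    trace <- vector("list", cfg$max_generations)
    hit_cap <- TRUE
    for (gen in seq_len(cfg$max_generations)) {
      eb <- which.max(fit)
      elite <- pop[eb, ]
      elite_fit <- unname(fit[eb])
      trace[[gen]] <- data.frame(generation = gen, elite = elite_fit,
                                 mean = mean(fit[is.finite(fit)]),
                                 restarts = restarts)
      if (!is.null(cfg$stop_fitness) && elite_fit >= cfg$stop_fitness) {
        hit_cap <- FALSE
        break
      }
      sim <- mean(pop == matrix(elite, cfg$pop_size, nb, byrow = TRUE))
      if (sim >= cfg$restart_similarity) {
        # converged: keep the elite, re-randomize the rest
        pop <- rbind(elite,
                     matrix(stats::rbinom((cfg$pop_size - 1L) * nb, 1L, 0.5),
                            cfg$pop_size - 1L, nb))
        fit <- c(elite_fit, apply(pop[-1, , drop = FALSE], 1, evalg))
        restarts <- restarts + 1L
        next
      }
      tournament <- function() {
        ij <- sample.int(cfg$pop_size, 2L)
        ij[which.max(fit[ij])]
      }
      children <- matrix(0L, cfg$pop_size - 1L, nb)
      for (k in seq_len(cfg$pop_size - 1L)) {
        pa <- pop[tournament(), ]
        pb <- pop[tournament(), ]
        mask <- stats::rbinom(nb, 1L, 0.5) == 1L
        children[k, ] <- ifelse(mask, pa, pb)
      }
      pop <- rbind(elite, children)
      fit <- c(elite_fit, apply(children, 1, evalg))
    }
  })
  eb <- which.max(fit)
  rownames(pop) <- NULL
  list(best = unname(pop[eb, ]), best_fitness = unname(fit[eb]),
       trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
       population = pop, hit_cap = hit_cap)
}
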