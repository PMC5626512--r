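# Independent brute-force oracles and shared fixtures.

# Optimum of a linear objective over {A x = b, lb <= x <= ub} by vertex
# enumeration: every vertex is a basic solution (m basic variables, the
# rest at a bound). Exponential, for tiny fixtures only.
enum_lp_opt <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  best <- NULL
  bestv <- if (maximize) -Inf else Inf
  for (bs in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, bs, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nbs <- setdiff(seq_len(n), bs)
    k <- length(nbs)
    for (mask in seq_len(2^k) - 1L) {
      xn <- lb[nbs]
      if (k > 0) {
        bits <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
        xn[bits == 1L] <- ub[nbs][bits == 1L]
      }
      rhs <- b - if (k > 0) A[, nbs, drop = FALSE] %*% xn else 0
      xb <- solve(B, rhs)
      xv <- numeric(n)
      xv[bs] <- xb
      xv[nbs] <- xn
      if (all(xv >= lb - 1e-8) && all(xv <= ub + 1e-8)) {
        v <- sum(obj * xv)
        if ((maximize && v > bestv + 1e-12) ||
            (!maximize && v < bestv - 1e-12)) {
          bestv <- v
          best <- xv
        }
      }
    }
  }
  list(x = best, objective = bestv)
}

# FBA optimum by enumeration over the flux polytope of a model (+overrides)
enum_fba_growth <- function(model, overrides = NULL) {
  bb <- popfba:::merge_overrides(model, overrides)
  obj <- as.numeric(model$reactions == model$biomass)
  enum_lp_opt(obj, as.matrix(model$S), rep(0, length(model$metabolites)),
              bb$lb, bb$ub, maximize = TRUE)$objective
}

# minimum total flux at optimal growth for a fully irreversible model
# (then sum |v| = sum v is linear and vertex enumeration applies)
enum_pfba_total <- function(model, overrides = NULL) {
  stopifnot(all(model$lb >= 0))
  bb <- popfba:::merge_overrides(model, overrides)
  mu <- enum_fba_growth(model, overrides)
  # add the growth pin as an equality row
  A <- rbind(as.matrix(model$S),
             as.numeric(model$reactions == model$biomass))
  b <- c(rep(0, length(model$metabolites)), mu)
  enum_lp_opt(rep(1, length(model$reactions)), A, b, bb$lb, bb$ub,
              maximize = FALSE)$objective
}

# flux range of one reaction at a growth fraction, by enumeration
enum_fva_range <- function(model, reaction, fraction = 1, overrides = NULL) {
  bb <- popfba:::merge_overrides(model, overrides)
  mu <- enum_fba_growth(model, overrides)
  # biomass >= fraction*mu via slack s in [0, 1e6]: v_bio - s = fraction*mu
  A <- cbind(rbind(as.matrix(model$S),
                   as.numeric(model$reactions == model$biomass)),
             c(rep(0, length(model$metabolites)), -1))
  b <- c(rep(0, length(model$metabolites)), fraction * mu)
  obj <- c(as.numeric(model$reactions == reaction), 0)
  lo <- c(bb$lb, 0)
  hi <- c(bb$ub, 1e6)
  c(min = enum_lp_opt(obj, A, b, lo, hi, maximize = FALSE)$objective,
    max = enum_lp_opt(obj, A, b, lo, hi, maximize = TRUE)$objective)
}

# small linear chain: substrate uptake (cap 10) -> conversion -> biomass
chain_model <- function(uptake = 10) {
  mets <- c("a_e", "a_c", "b_c")
  ids <- c("EX_a", "tA", "aToB", "BIO")
  S <- matrix(0, 3, 4, dimnames = list(mets, ids))
  S["a_e", "EX_a"] <- -1
  S["a_e", "tA"] <- -1; S["a_c", "tA"] <- 1
  S["a_c", "aToB"] <- -1; S["b_c", "aToB"] <- 1
  S["b_c", "BIO"] <- -1
  metabolic_model(ids, mets, S, lb = c(-uptake, 0, 0, 0),
                  ub = rep(1000, 4), gpr = c("", "", "G1", ""),
                  biomass = "BIO", id = "chain", exchanges = "EX_a")
}

# two parallel equal-yield routes of different length (2 vs 3 reactions);
# all reactions irreversible so that total flux is linear in v
parallel_model <- function(uptake = 10) {
  mets <- c("a_c", "m1_c", "m2_c", "m3_c", "b_c")
  ids <- c("EX_a", "short1", "short2", "long1", "long2", "long3", "BIO")
  S <- matrix(0, 5, 7, dimnames = list(mets, ids))
  S["a_c", "EX_a"] <- 1 # substrate source, capped at `uptake`
  S["a_c", "short1"] <- -1; S["m1_c", "short1"] <- 1
  S["m1_c", "short2"] <- -1; S["b_c", "short2"] <- 1
  S["a_c", "long1"] <- -1; S["m2_c", "long1"] <- 1
  S["m2_c", "long2"] <- -1; S["m3_c", "long2"] <- 1
  S["m3_c", "long3"] <- -1; S["b_c", "long3"] <- 1
  S["b_c", "BIO"] <- -1
  metabolic_model(ids, mets, S, lb = rep(0, 7),
                  ub = c(uptake, rep(1000, 6)), gpr = rep("", 7),
                  biomass = "BIO", id = "parallel", exchanges = "EX_a")
}

# shared toy bundle, built once per test run
toy_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- toy_model_config()
      model <- make_toy_model(cfg)
      prot <- make_toy_proteomics(model, cfg, seed = 1)
      samples <- sample_population(250, prot$marginals, prot$corr,
                                   prot$calibration, seed = 42)
      pop <- suppressMessages(
        simulate_population(model, samples, prot$kcats_true))
      cache <<- list(cfg = cfg, model = model, prot = prot,
                     samples = samples, pop = pop)
    }
    cache
  }
})
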