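test_that("identical cells give identical growth; starved cells barely grow", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  one <- bundle$samples[1, , drop = FALSE]
  rep100 <- one[rep(1, 20), , drop = FALSE]
  pop <- suppressMessages(
    simulate_population(bundle$model, rep100, prot$kcats_true))
  expect_equal(length(unique(pop$growth)), 1L)
  # all counts at the sampling floor: essentially no capacity, no growth
  floor_cell <- matrix(2.87, 1, ncol(one), dimnames = dimnames(one))
  pop0 <- suppressMessages(
    simulate_population(bundle$model, floor_cell, prot$kcats_true))
  expect_lt(pop0$growth, 1e-2)
})

test_that("growth histogram is density-normalized over its fixed range", {
  h <- growth_histogram(rep(0.3, 100), nbins = 50, range = c(0, 0.7))
  expect_equal(sum(h$counts > 0), 1L) # all mass in one bin
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-12)
  # uniform growth rates produce near-flat densities
  set.seed(9)
  mu <- runif(50000, 0, 0.5)
  h2 <- growth_histogram(mu, nbins = 10, range = c(0, 0.5))
  expect_true(all(abs(h2$density - 2) / 2 < 0.05))
  expect_equal(sum(h2$density * diff(h2$breaks)), 1, tolerance = 1e-12)
})

test_that("toy population shows the shoulder-plus-glucose-bound-peak shape", {
  bundle <- toy_bundle()
  pop <- bundle$pop
  mu <- pop$growth[pop$feasible]
  # broad heterogeneity: slow tail well below the fast mode
  expect_gt(diff(range(mu)), 0.25)
  expect_lt(quantile(mu, 0.1), 0.6 * quantile(mu, 0.9))
  # most of the fastest decile saturates the glucose uptake bound
  thr <- quantile(mu, 0.9)
  top <- which(pop$feasible & pop$growth >= thr)
  cap <- bundle$cfg$glucose_uptake
  at_glc <- mean(abs(pop$fluxes[top, "EX_glc"]) >= 0.99 * cap)
  expect_gt(at_glc, 0.6)
  # the population overwhelmingly ferments (Crabtree behavior)
  expect_gt(mean(pop$fluxes[pop$feasible, "EX_etoh"] > 1e-6), 0.9)
})

test_that("marginal shape matters: gamma vs normal/uniform changes the histogram", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  for (fam in c("normal", "uniform")) {
    alt_samples <- sample_population(250, prot$marginals, prot$corr,
                                    prot$calibration, seed = 42, family = fam)
    alt <- suppressMessages(
      simulate_population(bundle$model, alt_samples, prot$kcats_true))
    ks <- suppressWarnings(
      ks.test(bundle$pop$growth[bundle$pop$feasible],
              alt$growth[alt$feasible]))$statistic
    expect_gt(unname(ks), 0.1)
  }
})

test_that("dropping half the protein constraints preserves the histogram shape", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  set.seed(13)
  keep <- sample(colnames(bundle$samples),
                 ceiling(ncol(bundle$samples) / 2))
  half <- suppressMessages(simulate_population(
    bundle$model, bundle$samples[, keep, drop = FALSE], prot$kcats_true))
  ks <- suppressWarnings(
    ks.test(bundle$pop$growth[bundle$pop$feasible],
            half$growth[half$feasible]))$statistic
  expect_lt(unname(ks), 0.2)
})

test_that("growth-normalized PCA recovers the respiration axis", {
  bundle <- toy_bundle()
  p <- flux_pca(bundle$pop, n_cells = 200, seed = 2)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
  # the dominant growth-independent axis is the fermentation-respiration
  # balance: fermentative reactions carry the top loadings and the ETC
  # loads with the opposite sign (more respiration, less overflow)
  l1 <- p$loadings[, 1]
  top <- names(sort(abs(l1), decreasing = TRUE))
  expect_true(any(c("EX_etoh", "PYRDC", "ALCD") %in% top[1:3]))
  expect_lt(sign(l1["EX_etoh"]) * sign(l1["ETC"]), 0)
  # the second axis is the amino-acid energy-salvage pathway
  l2 <- p$loadings[, 2]
  top2 <- names(sort(abs(l2), decreasing = TRUE))
  expect_true(any(c("EX_aa", "AAt", "AACAT") %in% top2[1:3]))
  # identical cells: zero variance everywhere
  one <- bundle$samples[rep(1, 30), , drop = FALSE]
  pop1 <- suppressMessages(
    simulate_population(bundle$model, one, bundle$prot$kcats_true))
  expect_error(flux_pca(pop1, n_cells = 30, seed = 1)) # no varying column
})

test_that("flux comparison reproduces hand-computed RMSD", {
  bundle <- toy_bundle()
  pop <- bundle$pop
  means <- colMeans(pop$fluxes[pop$feasible, c("GLYC1", "EX_etoh")])
  # reference equal to the computed means: zero RMSD
  cmp0 <- compare_fluxes(pop, means)
  expect_equal(cmp0$rmsd, 0, tolerance = 1e-12)
  # means (1,2) against reference (2,4): sqrt((1+4)/2)
  fake <- pop
  fake$fluxes[, "GLYC1"] <- 1
  fake$fluxes[, "EX_etoh"] <- 2
  cmp <- compare_fluxes(fake, c(GLYC1 = 2, EX_etoh = 4))
  expect_equal(cmp$rmsd, sqrt(2.5), tolerance = 1e-12)
  # single-reaction reference: plain absolute difference
  cmp1 <- compare_fluxes(fake, c(GLYC1 = 5))
  expect_equal(cmp1$rmsd, 4)
  expect_error(compare_fluxes(pop, c(NOPE = 1)), "not in model")
})

test_that("bound-uptake classification flags the amino-acid bimodality", {
  bundle <- toy_bundle()
  md <- toy_medium(bundle$cfg)
  # every cell at the maximum: (1, 0), not bimodal
  fake <- bundle$pop
  fake$fluxes[, "EX_aa"] <- -md[["EX_aa"]]
  r <- bound_uptake_fraction(fake, "EX_aa", md)
  expect_equal(r$at_max, 1)
  expect_equal(r$basal, 0)
  expect_false(r$bimodal)
  # the simulated population toggles between basal and maximal uptake
  r2 <- bound_uptake_fraction(bundle$pop, "EX_aa", md)
  expect_gt(r2$at_max, 0.05)
  expect_gt(r2$basal, 0.05)
  expect_true(r2$bimodal)
  expect_error(bound_uptake_fraction(bundle$pop, "EX_glc",
                                     md[c("EX_o2", "EX_aa")]),
               "not in the medium")
})
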