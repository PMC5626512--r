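test_that("complex kcats are harmonized to the group maximum, transitively", {
  mets <- c("a_c", "b_c", "c_c")
  ids <- c("SRC", "R1", "R2", "BIO")
  S <- matrix(0, 3, 4, dimnames = list(mets, ids))
  S["a_c", "SRC"] <- 1
  S["a_c", "R1"] <- -1; S["b_c", "R1"] <- 1
  S["b_c", "R2"] <- -1; S["c_c", "R2"] <- 1
  S["c_c", "BIO"] <- -1
  m <- metabolic_model(ids, mets, S, rep(0, 4), c(10, rep(1000, 3)),
                       c("", "G1 and G2", "G2 and G3", ""), "BIO")
  kt <- kcat_table(c("G1", "G2", "G3"), c(10, 1000, 100))
  h <- harmonize_complex_kcats(kt, m)
  # G2 bridges both complexes: everything rises to the overall max
  expect_equal(h$kcat, rep(1000, 3))
  # isozymes (OR only) stay untouched
  m2 <- metabolic_model(ids, mets, S, rep(0, 4), c(10, rep(1000, 3)),
                        c("", "G1 or G2", "", ""), "BIO")
  expect_equal(harmonize_complex_kcats(kt, m2)$kcat, kt$kcat)
})

test_that("doubling stops immediately when the target is already met", {
  fx <- make_doubling_fixture()
  res <- doubling_procedure(fx$model, fx$marginals, NULL, fx$calibration,
                            fx$kcats_true, medium = fx$medium,
                            target_mean_growth = 5, batch_size = 50,
                            seed = 2)
  expect_equal(nrow(res$log), 0L)
  expect_equal(res$kcats$kcat, fx$kcats_true$kcat)
})

test_that("a planted 100-fold deficit needs exactly ceiling(log2) doublings", {
  fx <- make_doubling_fixture(deficit = 100)
  # target: mean growth of a reference population under the correct kcat
  ref <- sample_population(400, fx$marginals, NULL, fx$calibration, seed = 99)
  target <- mean(suppressMessages(
    simulate_population(fx$model, ref, fx$kcats_true))$growth)
  res <- doubling_procedure(fx$model, fx$marginals, NULL, fx$calibration,
                            fx$kcats_planted, target_mean_growth = target,
                            batch_size = 200, seed = 5)
  expect_equal(nrow(res$log), ceiling(log2(fx$deficit)))
  expect_equal(unique(res$log$gene), fx$gene)
  expect_equal(res$kcats$kcat,
               fx$kcats_planted$kcat * 2^ceiling(log2(fx$deficit)))
  # every logged event doubles, and replay reproduces the final table
  expect_equal(res$log$new_kcat, 2 * res$log$old_kcat)
  replayed <- replay_doubling_log(fx$kcats_planted, res$log)
  expect_equal(replayed$kcat, res$kcats$kcat)
  # batch mean growth is non-decreasing along the log
  expect_true(all(diff(res$log$batch_mean_growth) > -0.05 * target))
})

test_that("an AND-complex limitation doubles every subunit in one event", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  # plant one glycolytic complex subunit low and relax until growth recovers
  kc <- prot$kcats_true
  kc$kcat[kc$gene == "GLY2"] <- kc$kcat[kc$gene == "GLY2"] / 100
  res <- doubling_procedure(bundle$model, prot$marginals, prot$corr,
                            prot$calibration, kc,
                            target_mean_growth = 0.2, batch_size = 60,
                            seed = 3, max_iter = 60)
  # every event on a complex-catalyzed reaction doubles all its subunits
  # simultaneously (one iteration, one reaction, several genes)
  for (it in unique(res$log$iteration)) {
    ev <- res$log[res$log$iteration == it, ]
    rxn <- ev$reaction[1]
    subunits <- gpr_genes(bundle$model$gpr_tree[[rxn]])
    if (length(subunits) > 1 && bundle$model$gpr_tree[[rxn]]$op == "and")
      expect_setequal(ev$gene, subunits)
  }
  # the choked glycolytic step was relaxed, and always as a whole complex
  glyc_events <- res$log[res$log$reaction == "GLYC1", ]
  expect_gt(nrow(glyc_events), 0)
  expect_setequal(unique(glyc_events$gene), c("GLY1", "GLY2"))
})

test_that("medium-limited growth is reported, not silently doubled", {
  fx <- make_doubling_fixture()
  expect_error(
    doubling_procedure(fx$model, fx$marginals, NULL, fx$calibration,
                       fx$kcats_true, target_mean_growth = 50,
                       batch_size = 30, seed = 1),
    "limited by medium")
})

test_that("lifting a kcat never decreases any cell's growth", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  samples <- bundle$samples[1:25, , drop = FALSE]
  base <- suppressMessages(
    simulate_population(bundle$model, samples, prot$kcats_planted))
  lifted_tab <- prot$kcats_planted
  lifted_tab$kcat[lifted_tab$gene == "PDC1"] <- 38000
  lifted <- suppressMessages(
    simulate_population(bundle$model, samples, lifted_tab))
  expect_true(all(lifted$growth >= base$growth - 1e-8))
})

test_that("genome fitness is deterministic and rewards the generating genome", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  ctx <- ga_context(bundle$model, prot$marginals, prot$corr,
                    prot$calibration, prot$kcats_planted)
  cfg <- ga_config(cells = 30, bins = 20, seed = 8)
  gstar <- as.integer(ctx$candidates %in% prot$planted_genes)
  th <- target_histogram(bundle$pop$growth[bundle$pop$feasible], cfg)
  f1 <- genome_fitness(gstar, ctx, th, cfg)
  expect_identical(f1, genome_fitness(gstar, ctx, th, cfg)) # same seed
  f0 <- genome_fitness(rep(0L, length(ctx$candidates)), ctx, th, cfg)
  expect_gt(f1, f0) # lifting the planted deficits beats lifting nothing
  # a gene outside the active pathways has no effect beyond sampling noise
  gdec <- gstar
  gdec[ctx$candidates == "DEC3g"] <- 1L # decoy is pinned to zero flux
  expect_equal(genome_fitness(gdec, ctx, th, cfg), f1, tolerance = 0.02)
})

test_that("micro-GA keeps its elite: monotone trace and restart survival", {
  bundle <- toy_bundle()
  prot <- bundle$prot
  ctx <- ga_context(bundle$model, prot$marginals, prot$corr,
                    prot$calibration, prot$kcats_planted)
  cfg <- ga_config(cells = 25, bins = 15, max_generations = 12,
                   restart_similarity = 0.8, seed = 31)
  th <- target_histogram(bundle$pop$growth[bundle$pop$feasible], cfg)
  res <- microga_select(ctx, th, cfg)
  expect_true(all(diff(res$trace$elite) >= 0)) # elitism contract
  expect_equal(res$best_fitness, max(res$trace$elite))
  # reproducible end to end
  res2 <- microga_select(ctx, th, cfg)
  expect_identical(res$best, res2$best)
  expect_identical(res$trace, res2$trace)
  # the elite survives restarts bit-for-bit: elite fitness never drops
  # across a generation in which a restart occurred
  if (max(res$trace$restarts) > 0) {
    jumps <- which(diff(res$trace$restarts) > 0)
    expect_true(all(res$trace$elite[jumps + 1] >= res$trace$elite[jumps]))
  }
})
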