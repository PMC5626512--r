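#!/usr/bin/env Rscript
# Thin command-line entry point over the popfba package.
#
#   Rscript scripts/popfba.R make-toy --dir out [--seed 1]
#   Rscript scripts/popfba.R simulate --dir out --cells 1000 [--seed 1]
#   Rscript scripts/popfba.R analyze --dir out
#
# make-toy writes the synthetic Crabtree-style fixture bundle (SBML model,
# marginals, correlations, kcats, medium); simulate samples a correlated
# population and runs parsimonious FBA per cell; analyze writes the
# growth histogram and flux summaries.

suppressPackageStartupMessages(library(popfba))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: popfba.R <make-toy|simulate|analyze> [options]")
cmd <- args[1L]
opt <- list(dir = "popfba_out", cells = 1000L, seed = 1L)
i <- 2L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown option: ", args[i])
  opt[[key]] <- if (is.integer(opt[[key]])) as.integer(args[i + 1L]) else args[i + 1L]
  i <- i + 2L
}
dir.create(opt$dir, showWarnings = FALSE, recursive = TRUE)
pth <- function(...) file.path(opt$dir, ...)

if (cmd == "make-toy") {
  cfg <- toy_model_config(seed = opt$seed)
  model <- make_toy_model(cfg, sbml_path = pth("toy_model.xml"))
  prot <- make_toy_proteomics(model, cfg, seed = opt$seed)
  write.table(prot$marginals, pth("marginals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(prot$corr$R), pth("correlations.tsv"),
              sep = "\t", quote = FALSE)
  write.table(prot$kcats_true, pth("kcats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- toy_medium(cfg)
  write.table(data.frame(exchange_id = names(md), max_uptake = unname(md)),
              pth("medium.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cat("toy fixture written to ", opt$dir, "\n", sep = "")
} else if (cmd == "simulate") {
  model <- read_sbml_fbc(pth("toy_model.xml"))
  marg <- utils::read.delim(pth("marginals.tsv"))
  Rm <- as.matrix(utils::read.delim(pth("correlations.tsv")))
  corr <- correlation_model(Rm)
  kc <- utils::read.delim(pth("kcats.tsv"))
  kcats <- kcat_table(kc$gene, kc$kcat, kc$provenance)
  cal <- calibration_model(1, 1, floor = 2.87)
  samples <- sample_population(opt$cells, marg, corr, cal, seed = opt$seed)
  pop <- simulate_population(model, samples, kcats)
  write.table(data.frame(cell = seq_along(pop$growth), growth = pop$growth,
                         feasible = pop$feasible),
              pth("growth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pop$fluxes, pth("fluxes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  print(pop)
} else if (cmd == "analyze") {
  g <- utils::read.delim(pth("growth.tsv"))
  h <- growth_histogram(g$growth[g$feasible])
  write.table(data.frame(mid = h$mids, density = h$density,
                         count = h$counts),
              pth("growth_histogram.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("cells: %d (%.1f%% feasible), mean growth %.4g/hr\n",
              nrow(g), 100 * mean(g$feasible),
              mean(g$growth[g$feasible])))
} else {
  stop("unknown subcommand: ", cmd)
}
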