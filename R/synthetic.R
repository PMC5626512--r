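# Synthetic test fixtures: a small Crabtree-style metabolic network and a
# matching proteomics/correlation/kcat bundle. The network carries the
# mechanism the method is designed to expose -- a high-yield respiratory
# pathway gated by a scarce electron-transport-chain subunit, so that
# realistic per-cell enzyme capacities force fermentative overflow even
# though plain FBA would respire -- at a scale where every solver step can be
# checked against brute force.

#' Configuration for the toy Crabtree-style model
#'
#' The default stoichiometry makes biomass ATP-limited: fermentation yields
#' 2 ATP per glucose, respiration adds `atp_per_nadh` per NADH, and biomass
#' consumes NADH along with pyruvate and ATP so that carbon diverted to
#' biomass keeps the redox balance closed. With the default enzyme
#' abundances a typical cell grows at roughly 0.4/hr with heavy ethanol
#' secretion, while the unconstrained model respires.
#'
#' @param glucose_uptake medium cap on glucose uptake (mmol/gDwt/hr).
#' @param aa_uptake medium cap on amino-acid uptake (mmol/gDwt/hr).
#' @param atp_per_nadh ATP yield of the lumped electron transport chain per
#'   NADH.
#' @param biomass_atp,biomass_aa,biomass_nadh biomass stoichiometry per
#'   unit growth rate (the precursor route adds 2 pyruvate + 30 ATP per
#'   unit through the biosynthesis step).
#' @param resp_mean_copies mean copy number of the scarce respiratory subunit
#'   (QCR8-like; about 97 per cell).
#' @param n_decoys number of zero-flux decoy reactions (0-3).
#' @param seed fixture seed.
#' @return a `toy_model_config` list.
#' @export
toy_model_config <- function(glucose_uptake = 20, aa_uptake = 0.78,
                             atp_per_nadh = 2,
                             biomass_atp = 70, biomass_aa = 0.1,
                             biomass_nadh = 10, resp_mean_copies = 97,
                             n_decoys = 3L, seed = 1L) {
  cfg <- list(glucose_uptake = glucose_uptake, aa_uptake = aa_uptake,
              atp_per_nadh = atp_per_nadh,
              biomass_atp = biomass_atp, biomass_aa = biomass_aa,
              biomass_nadh = biomass_nadh,
              resp_mean_copies = resp_mean_copies,
              n_decoys = as.integer(n_decoys), seed = as.integer(seed))
  if (cfg$atp_per_nadh <= 0) stop("atp_per_nadh must be positive")
  structure(cfg, class = "toy_model_config")
}

#' Build the toy Crabtree-style metabolic model
#'
#' About twenty reactions: glucose import (transporter-limited), lumped
#' glycolysis behind an AND-complex, a fermentative branch (pyruvate
#' decarboxylase + alcohol dehydrogenase, ethanol out), a respiratory branch
#' (lumped TCA plus an electron transport chain gated by a scarce subunit),
#' a capped amino-acid uptake with a catabolic shunt, ATP maintenance, a
#' biomass objective, and decoy reactions that parsimonious FBA must leave
#' at zero.
#'
#' @param cfg a [toy_model_config()].
#' @param sbml_path optional path; when given the model is also written as
#'   SBML L3+FBC.
#' @return a [metabolic_model()].
#' @export
make_toy_model <- function(cfg = toy_model_config(), sbml_path = NULL) {
  mets <- c("glc_e", "o2_e", "aa_e", "glc_c", "o2_c", "aa_c", "pyr_c",
            "fbp_c", "g3p_c", "pep_c",
            "acald_c", "etoh_c", "co2_c", "atp_c", "nadh_c", "bm_c")
  rx <- list(
    #        id          stoich (met = coef)                          lb    ub    gpr
    list("EX_glc",  c(glc_e = -1),                                   -cfg$glucose_uptake, 1000, ""),
    list("EX_o2",   c(o2_e = -1),                                    -1000, 1000, ""),
    list("EX_aa",   c(aa_e = -1),                                    -cfg$aa_uptake, 1000, ""),
    list("EX_etoh", c(etoh_c = -1),                                  0,     1000, ""),
    list("EX_co2",  c(co2_c = -1),                                   0,     1000, ""),
    list("GLCt",    c(glc_e = -1, glc_c = 1),                        0,     1000, "HXT1"),
    list("O2t",     c(o2_e = -1, o2_c = 1),                          0,     1000, ""),
    list("AAt",     c(aa_e = -1, aa_c = 1),                          0,     1000, "AAT1"),
    # glycolysis as a four-step chain of two-subunit complexes: the chain
    # capacity is the minimum over the steps, so no single enzyme (or its
    # omission) determines the glycolytic ceiling
    list("GLYC1",   c(glc_c = -1, atp_c = -1, fbp_c = 1),            0,     1000, "GLY1 and GLY2"),
    list("GLYC2",   c(fbp_c = -1, g3p_c = 2),                        0,     1000, "GLY3 and GLY4"),
    list("GLYC3",   c(g3p_c = -1, nadh_c = 1, atp_c = 1, pep_c = 1), 0,     1000, "GLY5 and GLY6"),
    list("GLYC4",   c(pep_c = -1, atp_c = 0.5, pyr_c = 1),           0,     1000, "GLY7 and GLY8"),
    list("PYRDC",   c(pyr_c = -1, acald_c = 1, co2_c = 1),           0,     1000, "PDC1 or PDC5"),
    list("ALCD",    c(acald_c = -1, nadh_c = -1, etoh_c = 1),        0,     1000, "ADH1"),
    list("TCA",     c(pyr_c = -1, nadh_c = 4, co2_c = 3),            0,     1000, "TCA1"),
    list("ETC",     stats::setNames(c(-1, -0.5, cfg$atp_per_nadh),
                                    c("nadh_c", "o2_c", "atp_c")),   0,     1000,
         "QCR1 and QCR2 and QCR6 and QCR7 and QCR8 and QCR9"),
    # redox-neutral amino-acid catabolism to ATP (glycine-cleavage-style
    # energy salvage). Deliberately low-yield: costlier in flux per ATP
    # than glycolysis, so parsimony trims it unless growth maximization
    # itself needs the extra ATP -- which is what makes its uptake bimodal
    list("AACAT",   c(aa_c = -1, atp_c = 0.5, co2_c = 1),            0,     1000, "AAC1"),
    # biomass-precursor biosynthesis: a second, ATP-independent way a cell
    # can be growth-limited (scarce BSY1 mirrors biosynthetic bottlenecks)
    list("BIOSYN",  c(pyr_c = -2, atp_c = -30, bm_c = 1),            0,     1000, paste(paste0("BSY", 1:10), collapse = " and ")),
    list("ATPM",    c(atp_c = -1),                                   0,     1000, ""),
    list("BIOMASS", stats::setNames(
      c(-1, -cfg$biomass_atp, -cfg$biomass_aa, -cfg$biomass_nadh),
      c("bm_c", "atp_c", "aa_c", "nadh_c")),                         0,     1000, "")
  )
  if (cfg$n_decoys >= 1) {
    # a two-reaction loop (parsimony must silence it) and a dead end
    mets <- c(mets, "dcy1_c")
    rx <- c(rx, list(list("DECa", c(pyr_c = -1, dcy1_c = 1), 0, 1000, "DEC1g"),
                     list("DECb", c(dcy1_c = -1, pyr_c = 1), 0, 1000, "DEC2g")))
  }
  if (cfg$n_decoys >= 3) {
    mets <- c(mets, "dcy2_c")
    rx <- c(rx, list(list("DECc", c(atp_c = -1, dcy2_c = 1), 0, 0, "DEC3g")))
  }
  ids <- vapply(rx, `[[`, character(1), 1)
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, ids))
  for (j in seq_along(rx)) S[names(rx[[j]][[2]]), j] <- rx[[j]][[2]]
  model <- metabolic_model(
    reactions = ids, metabolites = mets, S = S,
    lb = vapply(rx, `[[`, numeric(1), 3), ub = vapply(rx, `[[`, numeric(1), 4),
    gpr = vapply(rx, `[[`, character(1), 5),
    biomass = "BIOMASS", id = "toy_crabtree",
    exchanges = c("EX_glc", "EX_o2", "EX_aa", "EX_etoh", "EX_co2"))
  chk <- fba(model)
  if (chk$status != "optimal" || chk$growth <= 0)
    stop("toy model configuration is infeasible or growth-free (growth ",
         chk$growth, ")")
  if (!is.null(sbml_path)) write_sbml_fbc(model, sbml_path)
  model
}

#' Default medium for the toy model
#' @param cfg a [toy_model_config()].
#' @return named uptake-magnitude vector over the toy exchanges.
#' @export
toy_medium <- function(cfg = toy_model_config()) {
  c(EX_glc = cfg$glucose_uptake, EX_o2 = 1000, EX_aa = cfg$aa_uptake)
}

# configured mean copy numbers for the toy genes. The scarce respiratory
# subunit mirrors the ~97-copy situation of cytochrome c reductase subunit 8;
# glycolytic and fermentative enzymes are abundant.
toy_gene_means <- function(cfg = toy_model_config()) {
  c(HXT1 = 190000, GLY1 = 104000, GLY2 = 50000, GLY3 = 47000, GLY4 = 95000,
    GLY5 = 92000, GLY6 = 190000, GLY7 = 93000, GLY8 = 187000,
    PDC1 = 167000, PDC5 = 630, ADH1 = 150000,
    TCA1 = 5200, QCR1 = 1500, QCR2 = 2000, QCR6 = 300, QCR7 = 250,
    QCR8 = cfg$resp_mean_copies, QCR9 = 150,
    AAT1 = 8000, AAC1 = 3000,
    stats::setNames(rep(3000, 10), paste0("BSY", 1:10)),
    DEC1g = 5000, DEC2g = 5000, DEC3g = 5000)
}

# turnover numbers placing mean capacities in a realistic band (c ~ 3e-7):
# transporter ~23 (just above the 20 medium cap), glycolysis ~30,
# fermentation ~60, respiration throttled near 1.2 by the scarce subunit.
toy_true_kcats <- function(cfg = toy_model_config()) {
  c(HXT1 = 550, GLY1 = 1500, GLY2 = 3000, GLY3 = 3000, GLY4 = 1500,
    GLY5 = 3000, GLY6 = 1500, GLY7 = 3000, GLY8 = 1500,
    PDC1 = 1200, PDC5 = 1200, ADH1 = 1200,
    TCA1 = 2000, QCR1 = 2700, QCR2 = 2000, QCR6 = 13500, QCR7 = 16000,
    QCR8 = 40000, QCR9 = 26000,
    AAT1 = 1000, AAC1 = 3000,
    stats::setNames(rep(580, 10), paste0("BSY", 1:10)),
    DEC1g = 1000, DEC2g = 1000, DEC3g = 1000)
}

#' Generate the synthetic proteomics bundle for the toy model
#'
#' Produces gamma marginals over enzyme copy numbers (per-gene CVs drawn in
#' 0.2-0.8), a block correlation structure (positive within the fermentative
#' and respiratory gene blocks, negative across them), a turnover-number
#' table with deliberately under-estimated entries (planted 100-fold too
#' low: one glycolytic complex subunit and the major pyruvate decarboxylase
#' isozyme), and a ten-row calibration table generated exactly from a known
#' power law.
#'
#' The marginals are expressed directly in copy-number units and pair with
#' the identity calibration returned in the bundle (`a = 1`, `b = 1`, floor
#' 2.87), so sampled counts have the configured means.
#'
#' @param model the toy model.
#' @param cfg the [toy_model_config()] used to build it.
#' @param seed RNG seed for the CV draws.
#' @return list with `marginals`, `corr` ([correlation_model()]), `kcats_true`
#'   ([kcat_table()]), `kcats_planted` (with the planted-low entries),
#'   `planted_genes`, `planted_factor`, `calibration_rows`, `calibration`.
#' @export
make_toy_proteomics <- function(model, cfg = toy_model_config(), seed = 1L) {
  means <- toy_gene_means(cfg)
  genes <- names(means)
  # per-gene noise levels: transporters tight, complex subunits and the
  # biosynthetic bottleneck broad (all within the 0.1-1.0 CV band seen in
  # single-cell proteomics)
  cvs <- c(HXT1 = 0.35, GLY1 = 0.4, GLY2 = 0.5, GLY3 = 0.45, GLY4 = 0.4,
           GLY5 = 0.45, GLY6 = 0.4, GLY7 = 0.45, GLY8 = 0.4, PDC1 = 0.6,
           PDC5 = 0.3, ADH1 = 0.6, TCA1 = 0.7, QCR1 = 0.6, QCR2 = 0.6,
           QCR6 = 0.6, QCR7 = 0.6, QCR8 = 0.6, QCR9 = 0.6,
           AAT1 = 0.25, AAC1 = 0.3,
           stats::setNames(rep(0.12, 10), paste0("BSY", 1:10)),
           DEC1g = 0.5, DEC2g = 0.45, DEC3g = 0.6)[genes]
  shape <- 1 / cvs^2
  marginals <- data.frame(protein_id = genes, shape = shape,
                          scale = means / shape,
                          n_retained = 18L, stringsAsFactors = FALSE)
  rownames(marginals) <- NULL

  ferm <- c("HXT1", "GLY1", "GLY2", "PDC1", "PDC5", "ADH1")
  resp <- c("TCA1", "QCR2", "QCR8")
  R <- diag(length(genes))
  dimnames(R) <- list(genes, genes)
  R[ferm, ferm] <- 0.6
  R[resp, resp] <- 0.6
  R[ferm, resp] <- -0.3
  R[resp, ferm] <- -0.3
  diag(R) <- 1
  corr <- correlation_model(R)

  kc <- toy_true_kcats(cfg)
  kcats_true <- kcat_table(names(kc), unname(kc), "curated")
  planted_genes <- c("GLY2", "PDC1")
  planted_factor <- 100
  kcp <- kc
  kcp[planted_genes] <- kcp[planted_genes] / planted_factor
  kcats_planted <- kcat_table(names(kcp), unname(kcp),
                              ifelse(names(kcp) %in% planted_genes,
                                     "planted-low", "curated"))

  f <- c(5, 12, 30, 70, 160, 380, 900, 2100, 5000, 12000)
  calibration_rows <- data.frame(
    gene = paste0("CAL", seq_along(f)),
    mean_count = 2.87 * f^1.5577, mean_fluorescence = f, ratio = 1,
    stringsAsFactors = FALSE)

  list(marginals = marginals, corr = corr, kcats_true = kcats_true,
       kcats_planted = kcats_planted, planted_genes = planted_genes,
       planted_factor = planted_factor,
       calibration_rows = calibration_rows,
       calibration = calibration_model(a = 1, b = 1, floor = 2.87))
}

#' Minimal planted-deficit fixture for the doubling procedure
#'
#' A three-step chain -- substrate exchange (capped at `uptake`), a
#' transport/conversion step gated by a single enzyme, and a biomass sink --
#' in which growth is exactly `min(uptake, enzyme capacity)`. The enzyme's
#' turnover number is under-estimated by `deficit`, so the number of
#' capacity doublings needed to restore growth is analytically
#' `ceiling(log2(deficit))`.
#'
#' @param uptake medium cap on the substrate (mmol/gDwt/hr).
#' @param mean_copies mean enzyme copy number.
#' @param true_kcat correct turnover number (1/s); the default puts the mean
#'   enzyme capacity at about 12, comfortably above the uptake cap.
#' @param deficit factor by which the planted kcat is too low.
#' @param cv coefficient of variation of the enzyme marginal.
#' @return list with `model`, `marginals`, `kcats_true`, `kcats_planted`,
#'   `medium`, `calibration`, `gene`, `deficit`.
#' @export
make_doubling_fixture <- function(uptake = 10, mean_copies = 40000,
                                  true_kcat = 1000, deficit = 100,
                                  cv = 0.25) {
  mets <- c("s_e", "s_c")
  rx <- list(
    list("EX_s", c(s_e = -1),          -uptake, 1000, ""),
    list("St",   c(s_e = -1, s_c = 1), 0,       1000, "ENZ1"),
    list("BIO",  c(s_c = -1),          0,       1000, "")
  )
  ids <- vapply(rx, `[[`, character(1), 1)
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, ids))
  for (j in seq_along(rx)) S[names(rx[[j]][[2]]), j] <- rx[[j]][[2]]
  model <- metabolic_model(ids, mets, S,
                           lb = vapply(rx, `[[`, numeric(1), 3),
                           ub = vapply(rx, `[[`, numeric(1), 4),
                           gpr = vapply(rx, `[[`, character(1), 5),
                           biomass = "BIO", id = "doubling_chain",
                           exchanges = "EX_s")
  shape <- 1 / cv^2
  marginals <- data.frame(protein_id = "ENZ1", shape = shape,
                          scale = mean_copies / shape, n_retained = 18L,
                          stringsAsFactors = FALSE)
  list(model = model, marginals = marginals,
       kcats_true = kcat_table("ENZ1", true_kcat, "curated"),
       kcats_planted = kcat_table("ENZ1", true_kcat / deficit, "planted-low"),
       medium = c(EX_s = uptake),
       calibration = calibration_model(a = 1, b = 1, floor = 2.87),
       gene = "ENZ1", deficit = deficit)
}
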