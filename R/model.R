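#' Construct a metabolic model
#'
#' Container for a constraint-based metabolic model: stoichiometry, flux
#' bounds, reversibility, gene-protein-reaction rules and the biomass
#' objective.
#'
#' @param reactions character vector of reaction ids.
#' @param metabolites character vector of metabolite ids.
#' @param S stoichiometric matrix, metabolites x reactions (dense or sparse).
#' @param lb,ub default flux bounds per reaction (mmol/gDwt/hr).
#' @param gpr character vector of GPR strings per reaction (`""` for none).
#' @param biomass id of the biomass (objective) reaction.
#' @param id model identifier.
#' @param exchanges optional explicit exchange reaction set; when `NULL`,
#'   reactions touching exactly one metabolite are taken as exchanges.
#' @return an object of class `metabolic_model` with parsed GPR trees
#'   (`$gpr_tree`), the gene inventory (`$genes`) and the exchange reaction
#'   set (`$exchanges`).
#' @export
metabolic_model <- function(reactions, metabolites, S, lb, ub, gpr,
                            biomass, id = "model", exchanges = NULL) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  stopifnot(nrow(S) == length(metabolites), ncol(S) == length(reactions),
            length(lb) == length(reactions), length(ub) == length(reactions),
            length(gpr) == length(reactions))
  if (any(lb > ub)) stop("lb > ub for reaction(s): ",
                         paste(reactions[lb > ub], collapse = ", "))
  if (!biomass %in% reactions) stop("biomass reaction '", biomass, "' not in model")
  dimnames(S) <- list(metabolites, reactions)
  gpr_tree <- lapply(seq_along(reactions),
                     function(i) parse_gpr(gpr[i], reactions[i]))
  names(gpr_tree) <- reactions
  genes <- sort(unique(unlist(lapply(gpr_tree, gpr_genes))))
  if (is.null(exchanges)) {
    nmet <- Matrix::colSums(S != 0)
    exchanges <- reactions[nmet == 1]
  } else {
    stopifnot(all(exchanges %in% reactions))
  }
  m <- list(id = id, reactions = reactions, metabolites = metabolites,
            S = S, lb = stats::setNames(as.numeric(lb), reactions),
            ub = stats::setNames(as.numeric(ub), reactions),
            reversible = stats::setNames(lb < 0, reactions),
            gpr = stats::setNames(gpr, reactions), gpr_tree = gpr_tree,
            genes = genes, biomass = biomass,
            exchanges = exchanges)
  structure(m, class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic model '%s': %d reactions, %d metabolites, %d genes\n",
              x$id, length(x$reactions), length(x$metabolites),
              length(x$genes)))
  cat(sprintf("  biomass: %s; exchanges: %d\n", x$biomass,
              length(x$exchanges)))
  invisible(x)
}

#' Unit constants for capacity bounds
#'
#' The factor converting catalytic events per cell per second into
#' mmol/gDwt/hr: seconds per hour divided by the product of the dry mass of
#' one cell and the number of particles in a mmol. With the yeast defaults
#' (2.0e-11 g dry mass) the factor is 2.99e-7, conventionally quoted as
#' 3.0e-7 s cell^-1 mmol gDwt^-1 hr^-1.
#'
#' @param seconds_per_hour seconds in an hour.
#' @param cell_dry_mass average dry mass of one cell (g).
#' @param particles_per_mmol particles in a millimole.
#' @return list with the inputs and the derived conversion factor `c`.
#' @export
unit_constants <- function(seconds_per_hour = 3600,
                           cell_dry_mass = 2.0e-11,
                           particles_per_mmol = 6.02e20) {
  cc <- seconds_per_hour / (cell_dry_mass * particles_per_mmol)
  list(seconds_per_hour = seconds_per_hour, cell_dry_mass = cell_dry_mass,
       particles_per_mmol = particles_per_mmol, c = cc)
}

#' Convert an enzyme copy number into a flux capacity
#'
#' `v_max = N_copy * k_cat * c`.
#'
#' @param count enzyme copies per cell (vectorized).
#' @param kcat turnover number (1/s).
#' @param units constants from [unit_constants()].
#' @return capacity in mmol/gDwt/hr.
#' @export
protein_vmax <- function(count, kcat, units = unit_constants()) {
  if (any(count < 0)) stop("counts must be non-negative")
  if (any(kcat <= 0)) stop("kcat must be positive")
  count * kcat * units$c
}

#' Select turnover numbers from a candidate table
#'
#' Per gene: the largest value reported for a wild-type S. cerevisiae enzyme
#' is preferred; failing that, the largest value from any mutant or other
#' organism; genes with no record at all get the default (the largest
#' turnover number reported for a wild-type yeast enzyme, 38,000 1/s).
#'
#' @param records data frame with columns `gene`, `kcat` (1/s), `organism`,
#'   `wild_type` (logical).
#' @param genes genes the table must cover; defaults to those in `records`.
#' @param default_kcat fallback turnover number (1/s).
#' @return a `kcat_table`: data frame `gene`, `kcat`, `provenance`
#'   (`wild-type-Sc`, `other` or `default`).
#' @export
select_kcat <- function(records, genes = NULL, default_kcat = 38000) {
  if (nrow(records) && any(records$kcat <= 0))
    stop("turnover numbers must be positive")
  if (is.null(genes)) genes <- sort(unique(records$gene))
  is_sc_wt <- records$wild_type &
    grepl("cerevisiae|^Sc$|^S\\. cerevisiae$", records$organism,
          ignore.case = TRUE)
  rows <- lapply(genes, function(g) {
    mine <- records$gene == g
    if (any(mine & is_sc_wt)) {
      data.frame(gene = g, kcat = max(records$kcat[mine & is_sc_wt]),
                 provenance = "wild-type-Sc", stringsAsFactors = FALSE)
    } else if (any(mine)) {
      data.frame(gene = g, kcat = max(records$kcat[mine]),
                 provenance = "other", stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, kcat = default_kcat, provenance = "default",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "default_kcat") <- default_kcat
  class(out) <- c("kcat_table", "data.frame")
  out
}

#' Construct a kcat table directly
#' @param gene,kcat,provenance parallel vectors.
#' @param default_kcat fallback turnover number (1/s).
#' @export
kcat_table <- function(gene, kcat, provenance = "curated",
                       default_kcat = 38000) {
  if (any(kcat <= 0)) stop("turnover numbers must be positive")
  out <- data.frame(gene = gene, kcat = kcat,
                    provenance = rep_len(provenance, length(gene)),
                    stringsAsFactors = FALSE)
  attr(out, "default_kcat") <- default_kcat
  class(out) <- c("kcat_table", "data.frame")
  out
}

# named vector of turnover numbers covering `genes`, with defaults filled in
kcat_vector <- function(kcats, genes) {
  default_kcat <- attr(kcats, "default_kcat")
  if (is.null(default_kcat)) default_kcat <- 38000
  v <- stats::setNames(rep(default_kcat, length(genes)), genes)
  hit <- genes %in% kcats$gene
  v[hit] <- kcats$kcat[match(genes[hit], kcats$gene)]
  v
}

#' Apply a growth medium and gene knockouts to a model
#'
#' Exchange reactions named in the medium get their uptake (negative-flux)
#' lower bound set to minus the listed magnitude; all other exchanges are
#' closed for uptake (lower bound 0). Secretion bounds are untouched.
#' Reactions whose GPR evaluates to false under the knockouts are fixed to
#' zero flux.
#'
#' @param model a [metabolic_model()].
#' @param medium named numeric vector: exchange reaction id -> maximum uptake
#'   magnitude (mmol/gDwt/hr, >= 0). `NULL` leaves the model's exchange
#'   bounds untouched (e.g. to apply knockouts only); an empty vector closes
#'   every uptake.
#' @param knockouts character vector of inactivated genes.
#' @return the modified model.
#' @export
apply_medium_and_knockouts <- function(model, medium, knockouts = character()) {
  if (!is.null(medium)) {
    if (any(medium < 0)) stop("medium uptake magnitudes must be >= 0")
    unknown <- setdiff(names(medium), model$exchanges)
    if (length(unknown))
      stop("unknown exchange reaction(s): ", paste(unknown, collapse = ", "))
    model$lb[model$exchanges] <- pmax(model$lb[model$exchanges], 0)
    model$lb[names(medium)] <- -unname(medium)
  }
  bad_gene <- setdiff(knockouts, model$genes)
  if (length(bad_gene))
    stop("knockout gene(s) not in model: ", paste(bad_gene, collapse = ", "))
  if (length(knockouts)) {
    dead <- !vapply(model$gpr_tree, gpr_active, logical(1),
                    knockouts = knockouts)
    model$lb[dead] <- 0
    model$ub[dead] <- 0
  }
  model$medium <- medium
  model$knockouts <- knockouts
  model
}

#' Translate one cell's protein counts into reaction capacity bounds
#'
#' Every reaction whose GPR references at least one measured gene receives a
#' capacity override computed by [evaluate_gpr()] over the per-gene
#' capacities `count * kcat * c`. Enzyme copies are not partitioned across
#' the reactions an enzyme catalyzes: all copies are available to every
#' associated reaction.
#'
#' @param model a [metabolic_model()].
#' @param counts named numeric vector of one cell's enzyme copies.
#' @param kcats a [kcat_table()].
#' @param units constants from [unit_constants()].
#' @param default_bound bound representing "unconstrained".
#' @return a `cell_constraints` data frame: `reaction`, `vmax`, `genes`
#'   (comma-joined measured genes behind each bound).
#' @export
build_cell_bounds <- function(model, counts, kcats,
                              units = unit_constants(),
                              default_bound = 1000) {
  measured <- intersect(names(counts), model$genes)
  vmax_gene <- protein_vmax(counts[measured],
                            kcat_vector(kcats, measured)[measured], units)
  touched <- vapply(model$gpr_tree,
                    function(e) any(gpr_genes(e) %in% measured), logical(1))
  rx <- model$reactions[touched]
  vv <- vapply(rx, function(r)
    evaluate_gpr(model$gpr_tree[[r]], vmax_gene, default_bound), numeric(1))
  gg <- vapply(rx, function(r)
    paste(intersect(gpr_genes(model$gpr_tree[[r]]), measured),
          collapse = ","), character(1))
  out <- data.frame(reaction = rx, vmax = unname(vv), genes = unname(gg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cell_constraints", "data.frame")
  out
}

#' Read a medium specification from a TSV file
#'
#' Expects columns `exchange_id`, `max_uptake`.
#' @param path file path.
#' @return named numeric vector of uptake magnitudes.
#' @export
read_medium_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$max_uptake, df$exchange_id)
}

#' Read a kcat candidate table from a TSV file
#'
#' Expects columns `gene`, `kcat`, `organism`, `wild_type`.
#' @param path file path.
#' @export
read_kcat_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$wild_type <- as.logical(df$wild_type)
  df
}
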