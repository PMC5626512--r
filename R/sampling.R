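#' Quantile-normalize an expression matrix
#'
#' Forces every array (column) to share the same empirical distribution by
#' replacing each array's order statistics with the across-array means of the
#' order statistics; within-array ranks are preserved and ties receive the
#' mean of their target quantile values. The computation is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param m numeric genes x arrays matrix with at least 2 columns.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("quantile normalization needs at least 2 arrays")
  if (anyNA(m)) stop("expression matrix must not contain missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Estimate a gene-gene correlation model from expression data
#'
#' Optionally averages multiple probes per gene, computes Pearson
#' correlations across arrays, repairs the matrix to positive
#' semidefiniteness by eigenvalue clipping (followed by rescaling to a unit
#' diagonal), and stores the lower Cholesky factor used for correlated
#' sampling. Zero-variance genes get zero correlation to everything (unit
#' self-correlation) with a warning.
#'
#' @param m numeric matrix, rows = probes (or genes), columns = arrays.
#' @param probe_map optional named list mapping gene id -> character vector
#'   of row names of `m` to average; when `NULL` rows are taken as genes.
#' @param eig_floor eigenvalue clip level for the PSD repair.
#' @return an object of class `correlation_model` with fields `genes`, `R`
#'   (repaired correlation matrix) and `L` (lower triangular, `L %*% t(L)`
#'   equals `R` to 1e-8).
#' @export
compute_correlations <- function(m, probe_map = NULL, eig_floor = 1e-8) {
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("Pearson correlation needs at least 3 arrays")
  if (!is.null(probe_map)) {
    m <- do.call(rbind, lapply(probe_map, function(pr) {
      colMeans(m[pr, , drop = FALSE])
    }))
    rownames(m) <- names(probe_map)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  R <- suppressWarnings(stats::cor(t(m)))
  if (any(flat)) {
    warning("zero-variance gene(s) get zero correlations: ",
            paste(rownames(m)[flat], collapse = ", "))
    R[flat, ] <- 0
    R[, flat] <- 0
  }
  diag(R) <- 1
  correlation_model(R)
}

#' Construct a correlation model from a correlation matrix
#'
#' @param R symmetric matrix with unit diagonal; repaired to PSD by
#'   eigenvalue clipping if needed.
#' @param eig_floor eigenvalue clip level.
#' @export
correlation_model <- function(R, eig_floor = 1e-8) {
  R <- as.matrix(R)
  if (is.null(rownames(R))) rownames(R) <- colnames(R)
  if (is.null(rownames(R))) stop("correlation matrix must have gene names")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  R <- (R + t(R)) / 2
  Rt <- psd_repair(R, eig_floor)
  L <- t(chol(Rt))
  structure(list(genes = rownames(R), R = Rt, L = L),
            class = "correlation_model")
}

# nearest-ish PSD: clip eigenvalues at eig_floor, rescale to unit diagonal
psd_repair <- function(R, eig_floor = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(R)
  lam <- pmax(e$values, eig_floor)
  Rt <- e$vectors %*% (lam * t(e$vectors))
  d <- 1 / sqrt(diag(Rt))
  Rt <- Rt * tcrossprod(d)
  dimnames(Rt) <- dimnames(R)
  (Rt + t(Rt)) / 2
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("correlation model: %d genes, min eigenvalue %.3g\n",
              length(x$genes), min(eigen(x$R, symmetric = TRUE,
                                         only.values = TRUE)$values)))
  invisible(x)
}

#' Draw a correlated population of single-cell protein counts
#'
#' Gaussian copula (NORTA) sampling: correlated standard normals
#' `z = L %*% eps` are pushed through the normal CDF and the per-protein
#' gamma quantile functions, giving fluorescence values with exactly the
#' censored gamma marginals and the imposed latent correlation structure;
#' fluorescence is then converted to copy numbers through the calibration.
#' Proteins without correlation data are sampled independently.
#'
#' @param n_cells number of cells to draw.
#' @param marginals data frame with `protein_id`, `shape`, `scale` (as from
#'   [censor_distributions()]).
#' @param corr a [correlation_model()] or `NULL` for fully independent
#'   sampling; may cover any subset of the marginals.
#' @param cal a [calibration_model()].
#' @param seed integer seed; identical seeds give bit-identical populations.
#' @param family marginal family. `"gamma"` is the realistic choice;
#'   `"normal"` (truncated at zero) and `"uniform"` (on `[0, 2*mean]`) keep
#'   the same per-protein means and exist for sensitivity analyses of how
#'   much the marginal shape matters.
#' @return a `cells x proteins` matrix of copy numbers (class `cell_counts`),
#'   with the seed stored in `attr(, "seed")`.
#' @export
sample_population <- function(n_cells, marginals, corr = NULL, cal, seed = 1L,
                              family = c("gamma", "normal", "uniform")) {
  family <- match.arg(family)
  if (n_cells <= 0) stop("n_cells must be positive")
  if (nrow(marginals) == 0) stop("no marginals to sample")
  ids <- marginals$protein_id
  u <- matrix(NA_real_, n_cells, length(ids), dimnames = list(NULL, ids))
  with_local_seed(seed, {
    if (!is.null(corr)) {
      shared <- intersect(ids, corr$genes)
      if (length(shared)) {
        L <- corr$L[match(shared, corr$genes), match(shared, corr$genes),
                    drop = FALSE]
        # re-factor the subsetted correlation block
        if (length(shared) < length(corr$genes)) {
          Rsub <- corr$R[match(shared, corr$genes), match(shared, corr$genes),
                         drop = FALSE]
          L <- t(chol(psd_repair(Rsub)))
        }
        eps <- matrix(stats::rnorm(n_cells * length(shared)), n_cells)
        u[, shared] <- stats::pnorm(eps %*% t(L))
      }
      rest <- setdiff(ids, shared)
    } else {
      rest <- ids
    }
    if (length(rest))
      u[, rest] <- stats::runif(n_cells * length(rest))
  })
  sh <- rep(marginals$shape, each = n_cells)
  sc <- rep(marginals$scale, each = n_cells)
  f <- switch(family,
    gamma   = stats::qgamma(u, shape = sh, scale = sc),
    normal  = pmax(stats::qnorm(u, mean = sh * sc, sd = sqrt(sh) * sc), 0),
    uniform = stats::qunif(u, 0, 2 * sh * sc))
  counts <- fluorescence_to_count(f, cal)
  dim(counts) <- dim(u)
  dimnames(counts) <- dimnames(u)
  structure(counts, seed = seed, class = c("cell_counts", "matrix", "array"))
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read an expression matrix from a TSV file
#'
#' First column gene/probe id, remaining columns arrays.
#' @param path file path.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
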