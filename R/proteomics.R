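#' Censoring configuration for fluorescence distributions
#'
#' Settings for the multi-step quality-control filter applied to per-protein,
#' per-timepoint gamma fits of single-cell fluorescence before they are used
#' for sampling. Defaults follow the filtering rules developed for yeast
#' GFP-library chemostat measurements: distributions narrower than 0.1 A.U. in standard
#' deviation are deconvolution artefacts ("spikes"), per-protein outliers are
#' flagged at 1.5 interquartile ranges, at least 3 timepoints must survive,
#' the coefficients of variation of the surviving means and standard
#' deviations must stay below 0.5, and proteins dimmer than 7.98 A.U. are
#' considered unreliable.
#'
#' @param sd_floor minimum credible standard deviation (fluorescence A.U.).
#' @param iqr_factor multiplier on the interquartile range for the per-protein
#'   outlier fence.
#' @param min_timepoints minimum number of surviving timepoints per protein.
#' @param cv_max strict upper bound on the CV of surviving means and of
#'   surviving standard deviations.
#' @param fluor_floor minimum pooled mean fluorescence (A.U.).
#' @param required_timepoints number of timepoints a protein must have been
#'   measured at to enter the filter at all.
#' @return an object of class `censor_config`.
#' @export
censor_config <- function(sd_floor = 0.1, iqr_factor = 1.5,
                          min_timepoints = 3L, cv_max = 0.5,
                          fluor_floor = 7.98, required_timepoints = 18L) {
  cfg <- list(sd_floor = sd_floor, iqr_factor = iqr_factor,
              min_timepoints = as.integer(min_timepoints), cv_max = cv_max,
              fluor_floor = fluor_floor,
              required_timepoints = as.integer(required_timepoints))
  if (any(unlist(cfg) <= 0)) stop("all censor_config settings must be positive")
  structure(cfg, class = "censor_config")
}

#' Build a table of per-timepoint fluorescence distributions
#'
#' @param protein_id character vector of gene identifiers.
#' @param timepoint integer timepoint index per row.
#' @param shape,scale gamma parameters of the fluorescence distribution
#'   (scale in fluorescence A.U.).
#' @return a `data.frame` with derived `mean` (= shape * scale) and
#'   `sd` (= sqrt(shape) * scale) columns.
#' @export
fluorescence_distributions <- function(protein_id, timepoint, shape, scale) {
  if (length(protein_id) == 0) stop("empty fluorescence distribution table")
  bad <- !is.finite(shape) | !is.finite(scale) | shape <= 0 | scale <= 0
  if (any(bad))
    stop("non-positive gamma parameters for protein(s): ",
         paste(unique(protein_id[bad]), collapse = ", "))
  df <- data.frame(protein_id = as.character(protein_id),
                   timepoint = as.integer(timepoint),
                   shape = as.numeric(shape), scale = as.numeric(scale),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("protein_id", "timepoint")]))
    stop("duplicate (protein_id, timepoint) rows")
  df$mean <- df$shape * df$scale
  df$sd <- sqrt(df$shape) * df$scale
  df
}

#' Censor unreliable fluorescence distributions
#'
#' Applies, in order: (1) drop proteins not measured at all
#' `required_timepoints` timepoints; (2) drop individual distributions with
#' standard deviation below `sd_floor`; (3) per protein, drop distributions
#' whose mean or standard deviation falls outside the fence
#' `[Q25 - k*IQR, Q75 + k*IQR]` computed (type-7 quantiles) from that
#' protein's remaining values, re-applied until nothing more falls outside
#' the recomputed fence; (4) drop proteins with fewer than
#' `min_timepoints` survivors; (5) drop proteins whose CV of surviving means
#' or CV of surviving standard deviations is not strictly below `cv_max`;
#' (6) drop proteins whose pooled mean fluorescence is below `fluor_floor`.
#'
#' Surviving timepoints are pooled into a single gamma marginal per protein by
#' averaging the per-timepoint means and variances and refitting by the
#' method of moments (shape = mean^2/var, scale = var/mean).
#'
#' @param distros a data frame as returned by [fluorescence_distributions()].
#' @param cfg a [censor_config()].
#' @return list with `marginals` (data frame: `protein_id`, `shape`, `scale`,
#'   `n_retained`), `survivors` (the retained rows of `distros`), and
#'   `report` (named removal counts per step, in distributions).
#' @export
censor_distributions <- function(distros, cfg = censor_config()) {
  if (nrow(distros) == 0) stop("empty fluorescence distribution table")
  bad <- distros$shape <= 0 | distros$scale <= 0
  if (any(bad))
    stop("non-positive gamma parameters for protein(s): ",
         paste(unique(distros$protein_id[bad]), collapse = ", "))
  if (is.null(distros$mean)) distros$mean <- distros$shape * distros$scale
  if (is.null(distros$sd)) distros$sd <- sqrt(distros$shape) * distros$scale

  report <- c(incomplete_protein = 0L, sd_floor = 0L, iqr_outlier = 0L,
              too_few_timepoints = 0L, cv_too_high = 0L, dim_protein = 0L)
  d <- distros

  # (1) proteins must have the full timepoint series
  ntp <- table(d$protein_id)
  drop1 <- names(ntp)[ntp < cfg$required_timepoints]
  report["incomplete_protein"] <- sum(d$protein_id %in% drop1)
  d <- d[!d$protein_id %in% drop1, , drop = FALSE]

  # (2) spike filter on standard deviations
  keep <- d$sd >= cfg$sd_floor
  report["sd_floor"] <- sum(!keep)
  d <- d[keep, , drop = FALSE]

  # (3) per-protein IQR fence on means and sds, re-applied until no further
  # distribution falls outside the recomputed fence (fixed point), so the
  # whole censoring pass is idempotent
  if (nrow(d)) {
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$protein_id), function(ix) {
      repeat {
        ok <- iqr_inside(d$mean[ix], cfg$iqr_factor) &
          iqr_inside(d$sd[ix], cfg$iqr_factor)
        if (all(ok)) break
        ix <- ix[ok]
      }
      ix
    }), use.names = FALSE)
    report["iqr_outlier"] <- nrow(d) - length(keep)
    d <- d[sort(keep), , drop = FALSE]
  }

  # (4) minimum surviving timepoints
  ntp <- table(d$protein_id)
  drop4 <- names(ntp)[ntp < cfg$min_timepoints]
  report["too_few_timepoints"] <- sum(d$protein_id %in% drop4)
  d <- d[!d$protein_id %in% drop4, , drop = FALSE]

  # (5) retain iff both CVs strictly below cv_max
  if (nrow(d)) {
    cv <- function(x) stats::sd(x) / mean(x)
    ok <- vapply(split(d, d$protein_id), function(p) {
      cv(p$mean) < cfg$cv_max && cv(p$sd) < cfg$cv_max
    }, logical(1))
    drop5 <- names(ok)[!ok]
    report["cv_too_high"] <- sum(d$protein_id %in% drop5)
    d <- d[!d$protein_id %in% drop5, , drop = FALSE]
  }

  # (6) dim proteins
  if (nrow(d)) {
    pooled <- vapply(split(d$mean, d$protein_id), mean, numeric(1))
    drop6 <- names(pooled)[pooled < cfg$fluor_floor]
    report["dim_protein"] <- sum(d$protein_id %in% drop6)
    d <- d[!d$protein_id %in% drop6, , drop = FALSE]
  }

  marginals <- pool_marginals(d, cfg)
  list(marginals = marginals, survivors = d, report = report)
}

# single-protein IQR fence membership, type-7 quantiles
iqr_inside <- function(x, k) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x >= q[1] - k * iqr & x <= q[2] + k * iqr
}

# moment-pooling of surviving timepoints into one gamma marginal per protein
pool_marginals <- function(d, cfg) {
  if (nrow(d) == 0)
    return(data.frame(protein_id = character(), shape = numeric(),
                      scale = numeric(), n_retained = integer(),
                      stringsAsFactors = FALSE))
  sp <- split(d, d$protein_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    mu <- mean(p$mean)
    va <- mean(p$sd^2)
    data.frame(protein_id = p$protein_id[1], shape = mu^2 / va,
               scale = va / mu, n_retained = nrow(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Fit the fluorescence-to-copy-number calibration
#'
#' Ordinary least squares of `ln(mean_count * media_ratio)` on
#' `ln(mean_fluorescence)`. The exponent is the slope, the coefficient is the
#' exponentiated intercept, and the sampling floor is set equal to the
#' coefficient (the copy number implied by one fluorescence unit, below which
#' measurements are unreliable).
#'
#' @param rows data frame with columns `mean_count`, `mean_fluorescence` and
#'   `ratio` (media expression ratio; use 1 when no rescaling applies).
#' @return an object of class `calibration_model` with fields `a`
#'   (coefficient, copies * A.U.^-b), `b` (exponent) and `floor` (copies).
#' @export
fit_calibration <- function(rows) {
  req <- c("mean_count", "mean_fluorescence", "ratio")
  if (!all(req %in% names(rows))) stop("rows must have columns ", paste(req, collapse = ", "))
  if (nrow(rows) < 2) stop("calibration requires at least 2 rows")
  if (any(rows$mean_count <= 0 | rows$mean_fluorescence <= 0 | rows$ratio <= 0))
    stop("calibration values must be strictly positive")
  fit <- stats::lm(log(mean_count * ratio) ~ log(mean_fluorescence), data = rows)
  b <- unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  calibration_model(a = a, b = b)
}

#' Construct a calibration model directly
#'
#' @param a power-law coefficient (copies * A.U.^-b), > 0.
#' @param b power-law exponent, > 0.
#' @param floor copy-number floor; defaults to `a`.
#' @export
calibration_model <- function(a, b, floor = a) {
  if (a <= 0 || b <= 0 || floor <= 0)
    stop("calibration parameters must be strictly positive")
  structure(list(a = a, b = b, floor = floor), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration: copies = %.4g * f^%.4f (floor %.4g copies)\n",
              x$a, x$b, x$floor))
  invisible(x)
}

#' Convert fluorescence to protein copy number
#'
#' Evaluates the power-law calibration `a * f^b` and floors the result, so no
#' sampled enzyme ever has fewer copies than the calibration floor.
#'
#' @param f fluorescence values (A.U.), non-negative; vectorized.
#' @param cal a [calibration_model()].
#' @return copy numbers, bounded below by `cal$floor`.
#' @export
fluorescence_to_count <- function(f, cal) {
  if (any(!is.finite(f)) || any(f < 0)) stop("fluorescence must be finite and non-negative")
  pmax(cal$a * f^cal$b, cal$floor)
}

#' Rescale protein counts between growth media
#'
#' Multiplies each protein's copy number by its media expression ratio
#' (default 1 for proteins absent from the table) and re-applies the
#' calibration floor, so no rescaled count drops below it.
#'
#' @param counts named numeric vector (or cells x proteins matrix with column
#'   names) of copy numbers.
#' @param ratios named numeric vector of multiplicative ratios.
#' @param cal a [calibration_model()] supplying the floor.
#' @return rescaled counts, same shape as `counts`.
#' @export
rescale_counts <- function(counts, ratios, cal) {
  if (any(ratios <= 0)) stop("rescale ratios must be strictly positive")
  ids <- if (is.matrix(counts)) colnames(counts) else names(counts)
  if (is.null(ids)) stop("counts must be named by protein")
  r <- rep(1, length(ids))
  hit <- ids %in% names(ratios)
  r[hit] <- ratios[ids[hit]]
  out <- if (is.matrix(counts)) sweep(counts, 2, r, `*`) else counts * r
  pmax(out, cal$floor)
}

#' Read fluorescence distributions from a TSV file
#'
#' Expects columns `protein_id`, `timepoint`, `shape`, `scale`.
#' @param path file path.
#' @export
read_fluorescence_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fluorescence_distributions(df$protein_id, df$timepoint, df$shape, df$scale)
}

#' Read a calibration table from a TSV file
#'
#' Expects columns `gene`, `mean_count`, `mean_fluorescence`, `ratio`. The
#' ten-protein table used for the published yeast calibration ships with the
#' package: `system.file("extdata", "calibration_proteins.tsv", package =
#' "popfba")`.
#' @param path file path.
#' @export
read_calibration_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
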