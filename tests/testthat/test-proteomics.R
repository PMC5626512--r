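# helper: a clean 18-timepoint protein with specified means/CV
make_protein <- function(id, means, cv = 0.2) {
  shape <- 1 / cv^2
  fluorescence_distributions(rep(id, length(means)),
                             seq_along(means) - 1L,
                             rep(shape, length(means)),
                             means / shape)
}

test_that("censoring applies the documented steps in order", {
  cfg <- censor_config()
  # a protein whose 18 timepoints are identical survives untouched
  clean <- make_protein("CLEAN", rep(50, 18))
  res <- censor_distributions(clean, cfg)
  expect_equal(sum(res$report), 0L)
  expect_equal(res$marginals$protein_id, "CLEAN")
  expect_equal(res$marginals$n_retained, 18L)
  # pooled marginal preserves the moments
  expect_equal(res$marginals$shape * res$marginals$scale, 50, tolerance = 1e-9)

  # a timepoint with sd below the floor is removed as a spike
  spiky <- clean
  spiky$sd[1] <- 0.05
  spiky$scale[1] <- spiky$sd[1]^2 / spiky$mean[1]
  spiky$shape[1] <- spiky$mean[1] / spiky$scale[1]
  res2 <- censor_distributions(spiky, cfg)
  expect_equal(unname(res2$report["sd_floor"]), 1L)
  expect_equal(res2$marginals$n_retained, 17L)

  # an 18-timepoint protein with one wild mean loses it to the IQR fence
  means <- c(rep(10, 17), 100)
  out <- make_protein("OUT", means)
  # hand-computed type-7 quartiles of the 18 means: Q3 + 1.5 IQR < 100
  q <- quantile(out$mean, c(.25, .75), type = 7)
  expect_true(100 > q[2] + 1.5 * (q[2] - q[1]))
  res3 <- censor_distributions(out, cfg)
  expect_equal(unname(res3$report["iqr_outlier"]), 1L)
  expect_equal(res3$marginals$n_retained, 17L)
})

test_that("protein-level filters: completeness, CV and dimness", {
  cfg <- censor_config()
  short <- make_protein("SHORT", rep(50, 10)) # only 10 of 18 timepoints
  noisy <- make_protein("NOISY", seq(10, 180, length.out = 18)) # CV of means >= 0.5
  dim_p <- make_protein("DIM", rep(5, 18)) # below 7.98 A.U.
  clean <- make_protein("CLEAN", rep(50, 18))
  all4 <- rbind(short, noisy, dim_p, clean)
  res <- censor_distributions(all4, cfg)
  expect_equal(res$marginals$protein_id, "CLEAN")
  expect_equal(unname(res$report["incomplete_protein"]), 10L)
  expect_equal(unname(res$report["cv_too_high"]), 18L)
  expect_equal(unname(res$report["dim_protein"]), 18L)
  # removal counts sum to input minus retained
  expect_equal(sum(res$report), nrow(all4) - nrow(res$survivors))
})

test_that("censoring is idempotent on realistic spike-contaminated data", {
  cfg <- censor_config()
  set.seed(7)
  dfs <- lapply(1:25, function(i) {
    mu <- exp(runif(1, log(10), log(500)))
    means <- mu * exp(rnorm(18, 0, 0.15))
    p <- make_protein(paste0("P", i), means, cv = runif(1, 0.15, 0.3))
    if (i %% 4 == 0) { # plant a deconvolution spike
      p$mean[1] <- mu * 10
      p$sd[1] <- 0.05
      p$scale[1] <- p$sd[1]^2 / p$mean[1]
      p$shape[1] <- p$mean[1] / p$scale[1]
    }
    p
  })
  d <- do.call(rbind, dfs)
  first <- censor_distributions(d, cfg)
  # re-censor the survivors; the completeness requirement is the entry
  # criterion on raw series, so it is relaxed to the surviving counts
  cfg2 <- cfg
  cfg2$required_timepoints <- cfg$min_timepoints
  second <- censor_distributions(first$survivors, cfg2)
  expect_equal(second$survivors, first$survivors)
  expect_equal(sum(second$report), 0L)
})

test_that("calibration fit recovers exact power laws and the table fit", {
  # two points on the identity line
  rows <- data.frame(mean_count = c(10, 100), mean_fluorescence = c(10, 100),
                     ratio = 1)
  cal <- fit_calibration(rows)
  expect_equal(cal$a, 1, tolerance = 1e-9)
  expect_equal(cal$b, 1, tolerance = 1e-9)
  # exact log-linear data with a media ratio
  f <- c(3, 17, 80, 420, 2000)
  rows2 <- data.frame(mean_count = 3 * f^1.5 / 0.8, mean_fluorescence = f,
                      ratio = 0.8)
  cal2 <- fit_calibration(rows2)
  expect_equal(cal2$a, 3, tolerance = 1e-9)
  expect_equal(cal2$b, 1.5, tolerance = 1e-9)
  # property: any (a, b) is recovered from noiseless data
  set.seed(3)
  for (i in 1:10) {
    a <- exp(runif(1, -1, 3))
    b <- runif(1, 0.5, 2.5)
    f <- sort(exp(runif(5, 0, 8)))
    rows3 <- data.frame(mean_count = a * f^b, mean_fluorescence = f, ratio = 1)
    cal3 <- fit_calibration(rows3)
    expect_equal(cal3$a, a, tolerance = 1e-9)
    expect_equal(cal3$b, b, tolerance = 1e-9)
  }
  # the packaged ten-protein table reproduces the published constants
  tab <- read_calibration_tsv(system.file("extdata", "calibration_proteins.tsv",
                                          package = "popfba"))
  cal4 <- fit_calibration(tab)
  expect_equal(cal4$a, 2.87, tolerance = 0.02)
  expect_equal(cal4$b, 1.5577, tolerance = 0.02)
  expect_error(fit_calibration(rows[1, ]), "2 rows")
  expect_error(fit_calibration(transform(rows, ratio = -1)), "positive")
})

test_that("fluorescence conversion floors, grows monotonically, rescales", {
  cal <- calibration_model(2.87, 1.5577)
  expect_equal(fluorescence_to_count(1, cal), 2.87)
  expect_equal(fluorescence_to_count(0.5, cal), 2.87) # below-floor input
  expect_equal(fluorescence_to_count(100, cal), 2.87 * 100^1.5577)
  f <- sort(runif(50, 0, 50))
  counts <- fluorescence_to_count(f, cal)
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts >= cal$floor))
  expect_error(fluorescence_to_count(-1, cal), "non-negative")

  x <- c(A = 100, B = 4, C = 7)
  out <- rescale_counts(x, c(A = 0.5, B = 0.1), cal)
  expect_equal(unname(out["A"]), 50)
  expect_equal(unname(out["B"]), 2.87) # 0.4 re-floored
  expect_equal(unname(out["C"]), 7) # absent from table: unchanged
  expect_error(rescale_counts(x, c(A = 0), cal), "positive")
})
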