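test_that("FBA solves the linear chain and honors enzyme overrides", {
  ch <- chain_model(uptake = 10)
  s <- fba(ch)
  expect_equal(s$status, "optimal")
  expect_equal(s$growth, 10)
  expect_true(max(abs(as.matrix(ch$S) %*% s$fluxes)) < 1e-6)
  # an enzyme capacity of 4 on the conversion step transfers to growth
  ov <- data.frame(reaction = "aToB", vmax = 4, genes = "G1",
                   stringsAsFactors = FALSE)
  s2 <- fba(ch, ov)
  expect_equal(s2$growth, 4)
})

test_that("capping the respiratory enzyme flips the toy model to fermentation", {
  bundle <- toy_bundle()
  m <- bundle$model
  unconstrained <- pfba(m)
  expect_equal(unname(unconstrained$fluxes["EX_etoh"]), 0, tolerance = 1e-6)
  expect_lt(unname(unconstrained$fluxes["EX_o2"]), -1) # breathing
  ov <- data.frame(reaction = "ETC", vmax = 1.2, genes = "QCR8",
                   stringsAsFactors = FALSE)
  constrained <- pfba(m, ov)
  expect_gt(unname(constrained$fluxes["EX_etoh"]), 1) # overflow to ethanol
  expect_lt(constrained$growth, unconstrained$growth)
})

test_that("FBA matches vertex enumeration on small fixtures", {
  ch <- chain_model()
  expect_equal(fba(ch)$growth, enum_fba_growth(ch), tolerance = 1e-8)
  pm <- parallel_model()
  expect_equal(fba(pm)$growth, enum_fba_growth(pm), tolerance = 1e-8)
  # with a random override on each fixture
  set.seed(17)
  for (rep in 1:5) {
    cap <- runif(1, 0.5, 8)
    ov <- data.frame(reaction = "aToB", vmax = cap, genes = "G1",
                     stringsAsFactors = FALSE)
    expect_equal(fba(ch, ov)$growth, enum_fba_growth(ch, ov),
                 tolerance = 1e-8)
  }
})

test_that("pFBA routes flux through the shorter of two equal-yield paths", {
  pm <- parallel_model(uptake = 10)
  p <- pfba(pm)
  expect_equal(p$growth, 10)
  expect_equal(unname(p$fluxes["short1"]), 10)
  expect_equal(unname(p$fluxes["long1"]), 0)
  # total flux equals the enumeration oracle in the irreversible fixture
  expect_equal(p$total_flux, enum_pfba_total(pm), tolerance = 1e-8)
  # a unique-optimum network: pFBA flux equals FBA flux
  ch <- chain_model()
  expect_equal(pfba(ch)$fluxes, fba(ch)$fluxes, tolerance = 1e-8)
})

test_that("relaxing the growth pin can only reduce total flux", {
  pm <- parallel_model(uptake = 10)
  full <- pfba(pm, optimality_fraction = 1.0)
  rel <- pfba(pm, optimality_fraction = 0.9)
  expect_gte(rel$growth, 0.9 * full$growth - 1e-9)
  expect_lte(rel$total_flux, full$total_flux + 1e-9)
})

test_that("FVA brackets fluxes and widens as optimality drops", {
  ch <- chain_model()
  # single path at 100%: min = max = pFBA flux everywhere
  r <- fva(ch, optimality_fraction = 1.0)
  p <- pfba(ch)
  expect_equal(r$min, unname(p$fluxes[r$reaction]), tolerance = 1e-7)
  expect_equal(r$max, unname(p$fluxes[r$reaction]), tolerance = 1e-7)
  # parallel branches at 100% without a pin range over [0, total]
  pm <- parallel_model()
  r2 <- fva(pm, reactions = c("short1", "long1"))
  expect_equal(r2$min, c(0, 0), tolerance = 1e-7)
  expect_equal(r2$max, c(10, 10), tolerance = 1e-7)
  # enumeration oracle agrees
  er <- enum_fva_range(pm, "short1")
  expect_equal(unname(er["min"]), r2$min[1], tolerance = 1e-8)
  expect_equal(unname(er["max"]), r2$max[1], tolerance = 1e-8)
  # pinning the total flux excludes the wasteful branch
  r3 <- fva(pm, reactions = c("short1", "long1"), pin_total_flux = TRUE)
  expect_lt(r3$max[2], 2e-6)
  # lowering the fraction weakly widens every interval
  bundle <- toy_bundle()
  ov <- build_cell_bounds(bundle$model, bundle$samples[1, ],
                          bundle$prot$kcats_true)
  f100 <- fva(bundle$model, ov, 1.0, reactions = c("GLYC1", "ETC", "EX_etoh"))
  f90 <- fva(bundle$model, ov, 0.9, reactions = c("GLYC1", "ETC", "EX_etoh"))
  expect_true(all(f90$min <= f100$min + 1e-7))
  expect_true(all(f90$max >= f100$max - 1e-7))
})

test_that("active bound detection uses relative tolerance", {
  ch <- chain_model()
  ov <- data.frame(reaction = "aToB", vmax = 4, genes = "G1",
                   stringsAsFactors = FALSE)
  s <- fba(ch, ov)
  expect_equal(active_bounds(s, ov), "aToB")
  fake <- s
  fake$fluxes["aToB"] <- 3.999999996
  expect_equal(active_bounds(fake, ov), "aToB") # within tolerance
  fake$fluxes["aToB"] <- 3.9
  expect_equal(active_bounds(fake, ov), character()) # clearly inside
  # a bound at or above the default is not a protein constraint
  ov2 <- data.frame(reaction = "aToB", vmax = 1000, genes = "G1",
                    stringsAsFactors = FALSE)
  expect_equal(active_bounds(fba(ch, ov2), ov2), character())
})

test_that("infeasible problems surface as status, not crashes", {
  ch <- chain_model()
  ch$lb["BIO"] <- 20 # force more growth than uptake allows
  s <- fba(ch)
  expect_equal(s$status, "infeasible")
  expect_equal(s$growth, 0)
})
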