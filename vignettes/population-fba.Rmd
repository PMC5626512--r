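---
title: "Population flux balance analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population flux balance analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfba)
```

## The problem

Bulk measurements hide the fact that isogenic cells express every enzyme at
different copy numbers. Because metabolic flux through a reaction can never
exceed the catalytic capacity of the enzyme pool behind it
(`v_max = N_copy * k_cat`, Michaelis–Menten saturation), cell-to-cell
variation in enzyme abundance translates directly into cell-to-cell
variation in attainable fluxes and growth rate. popfba builds *in silico*
populations of independent cells: each cell draws a full enzyme-abundance
state from experimentally derived single-cell distributions (with realistic
co-expression correlations), those abundances become reaction capacity
bounds on a genome-scale metabolic model, and parsimonious flux balance
analysis (pFBA) predicts the cell's growth rate and flux distribution. The
population of solutions is then analyzed for growth-rate structure,
metabolic phenotypes and constraint usage.

## From fluorescence to per-cell capacities

**Censoring.** Automated deconvolution of GFP fluorescence from
autofluorescence produces a fraction of pathological, extremely narrow
("spikey") per-timepoint gamma fits. `censor_distributions()` removes them
with a fixed sequence of filters: proteins must carry the full timepoint
series; distributions with standard deviation `< 0.1` A.U. are spikes;
per-protein outliers in mean or standard deviation beyond 1.5 interquartile
ranges are discarded (the fence is re-applied until a fixed point, which
makes the whole filter idempotent — a single pass is not, because removing a
point moves the quartiles); proteins keep at least 3 surviving timepoints,
must have coefficients of variation of their surviving means and standard
deviations strictly below 0.5, and a pooled mean fluorescence of at least
7.98 A.U. The surviving timepoints are pooled by averaging the per-timepoint
means and variances and refitting a gamma by the method of moments
(`shape = mean^2/var`, `scale = var/mean`). This pooling rule is a package
decision: it preserves exactly the two moments the quality-control steps
operate on; alternatives (pooling on the log scale, or sampling a timepoint
per cell) would preserve other features.

**Calibration.** Absolute scale comes from ten proteins whose copy numbers
were quantified independently by mass spectrometry (shipped in
`inst/extdata/calibration_proteins.tsv`). `fit_calibration()` regresses
`ln(count * media_ratio)` on `ln(fluorescence)`; the fitted power law is
`p = 2.87 * f^1.5577` with a floor of 2.87 copies (the copy number implied
by one fluorescence unit; dimmer signals are unreliable, so no sampled
enzyme ever falls below the floor, including after media rescaling).

**Units.** A copy number times a turnover number (1/s) becomes a flux bound
in mmol per gram dry weight per hour through
`c = 3600 / (2.0e-11 * 6.02e20) = 2.99e-7` (seconds per hour over cell dry
mass times particles per mmol), conventionally quoted as `3.0e-7`. The
package always computes with the exact value.

## Correlated sampling

Co-regulated genes co-vary across cells; ignoring that inflates the
independence of capacity bounds. `compute_correlations()` estimates
gene–gene Pearson correlations from expression arrays (probes averaged per
gene, arrays quantile-normalized via limma). Empirical correlation matrices
from finite arrays are routinely indefinite, so the matrix is repaired by
eigenvalue clipping at `1e-8` followed by rescaling to a unit diagonal
before Cholesky factorization.

`sample_population()` uses a Gaussian copula (NORTA): latent correlated
normals are pushed through the normal CDF and each protein's gamma quantile
function. The correlation is imposed on the latent scale — a deliberate
choice. The realized Pearson correlation of the gamma counts is slightly
attenuated relative to the latent target (the exact Spearman correlation
under the copula is `(6/pi) * asin(rho/2)`, which the tests verify), but the
marginals are preserved *exactly*, and the marginals are what the growth
machinery is most sensitive to. Proteins without correlation data are
sampled independently. Sampling is deterministic given a seed; one seeded
stream generates the whole population (R's generator has no counter-based
mode, so parallel per-cell streams are not used — populations are modest
enough that a single stream is not a bottleneck).

## Capacity bounds through GPR logic

`evaluate_gpr()` turns per-gene capacities into per-reaction bounds:
complex subunits (`and`) take the minimum — the scarcest subunit caps the
complex — and isozymes (`or`) take the sum. Two missing-data rules matter:
an `or` with any unmeasured alternative cannot cap the reaction (the default
bound of 1000 mmol/gDwt/hr applies), because the unmeasured isozyme could be
abundant; an `and` with at least one measured subunit is still capped by the
measured ones (a measured subunit is a valid ceiling regardless of its
partners). Enzyme copies are *not* partitioned among the reactions an enzyme
catalyzes — all copies are available to each associated reaction, a
conscious overestimate in the absence of localization data. Capacity bounds
are applied to the forward direction and symmetrically to the reverse of
reversible reactions (`upper_only = TRUE` restricts them to upper bounds).

## The linear-programming layer

FBA maximizes biomass flux over `{S v = 0, lb <= v <= ub}`; pFBA then holds
biomass at (a fraction of) its optimum — as an inequality with a `1e-9`
slack, to avoid pinning the LP exactly onto a degenerate vertex — and
minimizes total absolute flux via forward/backward variable splitting.
`fva()` brackets each reaction's flux at a growth fraction, optionally with
the total flux pinned to the parsimonious total plus a `1e-6` slack (the pin
tolerance is a package choice; the published analyses do not state one).

The solver is a dense bounded-variable two-phase primal simplex written for
this package, with Dantzig pricing, a Bland's-rule fallback after runs of
degenerate pivots, and periodic basis refactorization. It is validated in
the test suite against brute-force vertex enumeration on small networks and
against the simplex implementations in the boot and pracma packages where
those run. pFBA's stage-2 LP can itself be degenerate; the package returns
the solver's vertex and relies on FVA for robustness statements.

Infeasible cells (possible when sampled capacities cannot sustain the
imposed maintenance or medium) are flagged and recorded with growth 0; they
are excluded from flux analytics and histograms by default, with a message.

## Relaxing inconsistent turnover numbers

Curated turnover numbers mix organisms, mutants and assay conditions, and a
single 100-fold-low `k_cat` throttles every simulated cell. Two repair
strategies are provided.

**Iterative doubling** (`doubling_procedure()`): simulate a batch of cells,
tally which reaction sits at its protein-derived bound most often, and
double the turnover number behind it — the most abundant isozyme for `or`
rules (a complex alternative is as abundant as its scarcest measured
subunit), all subunits for `and` complexes. Before any doubling,
`harmonize_complex_kcats()` raises all subunits of a complex to the
group-maximum kcat, transitively across shared subunits. Each iteration
draws a fresh batch with seed `base + iteration`, so the stopping rule
(batch mean growth reaching the target) is never fit to one fixed
population. Ties in the tally break to the lexicographically smallest
reaction id, for determinism. If the target is unmet and no protein bound is
active, growth is limited by the medium and the procedure stops with an
error saying so.

**Micro genetic algorithm** (`microga_select()`): a binary genome chooses,
per candidate gene, whether to keep the curated kcat or lift it to
38,000 1/s (the largest turnover number reported for a wild-type yeast
enzyme); fitness is the negative sum of squared differences between the
simulated and target growth-rate histograms (50 bins on [0, 0.7]/hr by
default, covering the observed 0–0.57 range). The micro-GA formalism uses a
population of 10 genomes, strict elitism, and no mutation; the published
description leaves the operators unspecified, so the package uses standard
choices, all exposed in `ga_config()`: binary tournament selection, uniform
crossover, and a restart (keep the elite, re-randomize the rest) when the
population's mean bitwise similarity to the elite reaches 0.95. Every genome
in a run is evaluated on the same seeded cell sample, so fitness differences
reflect the genomes, not sampling noise; evaluations are memoized per bit
pattern. Replicate runs recover the planted deficits together with
degenerate extras — lifting a gene that never constrains growth costs the
fitness nothing — so the *intersection* of lifted sets across runs is the
meaningful core, mirroring how degeneracy manifests in the full-scale
analysis.

## Population analytics

`growth_histogram()` bins growth rates into a density-normalized histogram
over a fixed range (default 50 bins on [0, 0.7]/hr). `flux_pca()` samples
cells (default 1,000), divides each flux vector by the cell's growth rate to
isolate growth-independent pathway usage, drops zero-variance reactions and
runs covariance PCA — no per-reaction standardization and no rotation, so
components remain in flux units and align with pathways.
`compare_fluxes()` reports population-mean fluxes against a user-supplied
reference map and their root-mean-square difference; the reference is an
explicit argument because published flux sets differ in which reactions they
cover. `bound_uptake_fraction()` classifies cells as taking a substrate at
its maximum allowable rate versus a basal rate (at most 10% of the maximum,
configurable) and flags bimodality when both classes hold at least 5% of
cells and the middle holds at most 10%.

## The synthetic fixture and what it does (and does not) show

`make_toy_model()` builds a ~25-reaction Crabtree-style network: glucose
import through a transporter, glycolysis as a four-step chain of two-subunit
complexes, a fermentative branch to ethanol, a respiratory branch (lumped
TCA plus an electron transport chain gated by six subunits, one expressed at
~97 copies per cell), a capped amino-acid uptake with a low-yield catabolic
shunt, a ten-subunit biosynthesis step, a biomass objective and zero-flux
decoys. Respiration out-yields fermentation per glucose, so the
*unconstrained* model respires exclusively; sampled enzyme capacities
throttle the electron transport chain to about 1.2 mmol/gDwt/hr and flip the
population to fermentative overflow — the Crabtree effect emerges from the
proteomics constraints, not from an imposed oxygen cap.

Design notes on the fixture, all visible in `toy_model_config()`:

* Multi-subunit complexes are not decoration: because reaction capacity is
  the minimum over many measured subunits, omitting a random half of the
  protein constraints moves the capacity distribution only modestly — which
  is why real populations are robust to constraint omission, and what the
  corresponding test measures. Early single-subunit drafts of this fixture
  failed that property for structural reasons, not numerical ones.
* The amino-acid shunt yields 0.5 ATP per amino acid — deliberately costlier
  in flux per ATP than glycolysis, so parsimony trims it unless growth
  maximization needs it. Its uptake is therefore bimodal across the
  population (basal for precursor-limited cells, maximal for ATP-limited
  ones), reproducing the mechanism behind bimodal amino-acid utilization.
* Per-gene noise levels are fixed (CVs 0.12–0.8, within the band seen in
  single-cell proteomics), with block-positive correlations inside the
  fermentative and respiratory gene sets and negative correlations across
  them.
* `make_doubling_fixture()` is a separate three-reaction chain in which
  growth is exactly `min(uptake, enzyme capacity)`; with a turnover number
  planted 100-fold low, the number of doublings needed to restore growth is
  analytically `ceiling(log2(100)) = 7`, which pins the doubling procedure's
  arithmetic.

Passing the fixture-based tests shows the machinery — sampling, GPR logic,
LP solutions, relaxation, analytics — is correct at a scale where brute
force can check it. It does not show that a genome-scale run on the real
proteomics reproduces the published population statistics; that requires
the external yeast 7.6 reconstruction and the full proteomics and
microarray datasets, which the file readers accept but the package does not
ship.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use populations of 250–1,000
cells, batches of 50–400 cells for relaxation, and GA fitness evaluations of
25–40 cells — sizes chosen so the full suite exercises every code path in
minutes on a single core while keeping Monte-Carlo standard errors well
inside the asserted tolerances. All stochastic steps take explicit integer
seeds and are bit-reproducible given them.

## Known limitations

* Biomass composition is constant across the population; growth-rate
  dependent composition is not modeled.
* Enzyme copies are shared across compartments and across all reactions an
  enzyme catalyzes; no capacity partitioning.
* The dense simplex targets small and mid-size models; genome-scale models
  load and solve, but a sparse-basis solver would be needed for large
  population runs at that scale.
* GFP-fusion stability can bias measured protein counts upward; no
  correction is applied.
* Correlations are pairwise Pearson on the latent scale; no shrinkage or
  network inference.
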