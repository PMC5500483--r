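---
title: "Attributing coastal turbidity to river sediment sources: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing coastal turbidity to river sediment sources: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumetrace)
```

## The model and its assumptions

`plumetrace` treats coastal turbidity as the superposition of plumes
from point sources (river mouths) whose influence decays with distance
as a power law. For pixel $i$ and source group $j$:

$$y_i = \Big(\sum_j \beta_j d_{ij}^{-\alpha_{g(j)}}\Big) e^{\varepsilon_i},
\qquad \varepsilon_i \sim N(0, 1/\tau_y),$$

$$\beta_j = \theta\, S_j\, e^{\nu_j}, \qquad \nu_j \sim N(0, 1/\tau_\nu).$$

The assumptions this encodes, and their consequences:

* **Isotropic, phenomenological dispersion.** The power kernel is not a
  hydrodynamic model; it summarizes how influence falls off with
  straight-line (or optionally over-water) distance. Currents, tides
  and wind-driven transport appear only through the freedom to give
  groups of sources (e.g. two coasts of an island) different dispersion
  magnitudes $\alpha_g$. We store $\alpha > 0$ and apply it as the
  exponent $-\alpha$; reported values are decay magnitudes.
* **Multiplicative observation error.** Satellite turbidity errors
  scale with the signal, so the likelihood is Gaussian in
  $\log y$ — an exact transformation of the stated error model, not an
  approximation. This also means all pixels carry equal weight in
  *relative* terms.
* **Loadings anchor the attribution.** The contribution split between
  sources is weakly identified from imagery alone (many splits produce
  similar fields). Scaling $\beta_j$ by independently computed sediment
  loadings $S_j$, with lognormal deviations $\nu_j$ whose precision
  $\tau_\nu$ is itself estimated, constrains the ordering of influences
  to resemble the ordering of loadings while letting the data overrule
  it where the signal is strong.
* **No spatial autocorrelation in residuals**, no wind covariates, no
  bathymetry: deliberate scope limits.

Catchment loadings use the export-coefficient form
$S_k = \sum_l s_l\, p_{l,k}\, r_k\, f_{l,k}$ with two default land-use
classes (forested, deforested). The runoff proportion $p$ increases
with a catchment's mean wet-season rainfall; because only monotonicity
is scientifically established here, two curve forms are provided
(linear-capped, default, and saturating exponential), both configurable.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| grouping threshold | km | 5 | nearby mouths are not separately identifiable; single-linkage closure merges them |
| distance floor | km | 0.5 | removes the $d^{-\alpha}$ singularity at a mouth; below half a pixel it has no physical meaning |
| rescaling epsilon | — | $10^{-3}\bar y$ | anchors the minimum observation just above zero so no additive background term is needed |
| $\alpha$ prior | — | gamma(1, 0.1) | vague on the positive half-line |
| $\tau_y,\tau_\nu$ priors | — | gamma(0.01, 0.01) | conventional vague precision priors |
| $\log\theta$ prior | — | $N(0, 10)$ | vague scale between loading and turbidity units |
| chains × iterations | — | 2 × 3000 (1000 burn-in) | Gelman-Rubin needs ≥ 2 chains; batches in this package use 4000/1500 |
| convergence bound | — | GR < 1.05 for all parameters | fits failing it are flagged, and excluded (with counts) from recovery batches |

## Sampler design

The sampler is adaptive Metropolis-within-Gibbs, written in C++:

* $\log\theta$ has a conjugate Gaussian full conditional (it is a pure
  intercept on the log scale) and is drawn exactly.
* Each $\alpha_g$ uses a log-scale random walk whose acceptance ratio
  *integrates $\log\theta$ out analytically* (a partially collapsed
  blocked update). Without this, the strong $\alpha$–$\theta$ posterior
  correlation makes the $\alpha$ chain mix an order of magnitude more
  slowly.
* A "ridge move" proposes a joint shift of $\log\theta$ against all
  $\nu_j$; $\beta_j$ is invariant under it, so it explores the weakly
  identified direction at prior cost only.
* Proposal scales adapt toward 0.44 acceptance in batches of 50 during
  burn-in and are then frozen, so the post-burn-in kernel satisfies
  detailed balance. Chains are run sequentially from one seeded RNG
  stream with overdispersed starts; a seed fully determines the output.
* Prior-only mode (`likelihood = FALSE`) runs the same transition
  kernels with the data term removed; the tests verify that it
  reproduces prior moments. That check uses moderately informative test
  priors (gamma(2, 1), log-normal(0, 1)) because the default vague
  priors have Monte-Carlo moments too heavy-tailed to compare against.

The Gelman-Rubin statistic is
$\sqrt{\{(n-1)/n\,W + B/n\}/W}$, floored at 1 (the raw formula dips to
$\sqrt{(n-1)/n}$ for identical chains, which would read as
spuriously "better than converged"). `coda::gelman.diag` serves as an
independent oracle in the tests, and one test refits a small dataset in
JAGS and compares posterior means — a cross-implementation check of the
whole likelihood, prior and sampler stack.

## Model-selection statistics

* **DIC** uses $\bar D + p_D$ with $p_D = \bar D - D(\tilde\vartheta)$
  evaluated at the posterior **median** of each parameter. The textbook
  posterior-mean plug-in is parameterization-sensitive; with the
  strongly right-skewed posteriors of $\theta$, $e^{\nu}$ and misfit
  models it can land far outside the posterior bulk and produce large
  negative $p_D$ (we observed $p_D \approx -1300$ for a deliberately
  misspecified single-dispersion fit). The median plug-in keeps $p_D$
  near the effective parameter count and the model ordering coherent.
* **Predictive loss** is the Gelfand–Ghosh squared-error form
  ($k\to\infty$): goodness-of-fit plus posterior-predictive variance,
  computed on the log scale, where the error model is Gaussian.
* **Hold-out RMSE** compares withheld observations with the posterior
  mean of $\mu$ on the natural (standardized-turbidity) scale, with no
  lognormal mean correction; hold-out pixels are chosen uniformly at
  random by the fit seed and never enter the likelihood.

All three are pure functions of the stored chains plus data; reports can
be recomputed without refitting.

## What the simulator emulates — and what it does not

`simulation_scenario()` reproduces the idealized study conditions: a
straight coastline along the x-axis, three point sources at 100/200/300
km with equal loadings, a 30 × 10 lattice of ocean pixels reaching 100
km offshore, the power kernel with $\alpha = 1.25$, and lognormal
observation error with SD 0.5 on the log scale. One stated description
of the geometry (a "100 km" coastline) is inconsistent with sources at
100–300 km; we default to a 300 km coastline carrying those source
positions, and the extent is configurable so the shorter reading can be
run as well. Truth is $\beta_j = \theta S_j$ exactly; lognormal loading
deviations can be injected (`nu_sd`) for hierarchy-recovery
experiments, but default to zero.

The simulator does **not** emulate: anisotropic or advective transport,
tides, masked reef geometry, quality-flag dropouts, or spatial error
correlation. Passing recovery tests therefore demonstrates that the
estimator is consistent and nearly unbiased *under the model's own
assumptions*, not that those assumptions hold for any real coastline.

Replicate $r$ of a scenario derives its RNG stream from the scenario
seed and $r$ alone, so batches are reproducible and the same replicate
noise is shared across sweep settings (common random numbers).

### Precision limits of the recovery metrics

At the stated conditions (300 pixels, error SD 0.5), a single
replicate's posterior constrains the dispersion parameter to a few
percent and each contribution share to roughly 5–10% relative. Averaged
over 25 replicates, the mean relative error of the dispersion estimate
resolves bias at the ~0.5% level, but the *worst-source* share MRE
(a maximum over sources and sweep settings) inherits a ~1% standard
error per source and so fluctuates between roughly 1% and 3% across
batch seeds even though its expectation is near zero. The acceptance
script reports these statistics exactly as computed; they should be
read with that Monte-Carlo floor in mind.

Close, unequal sources are the documented hard case: when two sources
are nearly co-located, the likelihood constrains only their combined
influence, and the symmetric lognormal posterior on their log-ratio
pulls the *expected* share of the smaller source up and the larger
down. This is a mean effect with a right-skewed error distribution —
the median replicate shows little of it — so the tests assert the sign
of the batch-level MREs rather than a per-replicate sign count.

## The two-coast fixture

`mini_fiji_fixture()` builds a synthetic island case study entirely in
code: a finite rectangular landmass with ocean on both sides, seven
catchments (two of whose mouths sit 3 km apart, exercising the 5-km
aggregation), heavier loadings on the deforested north coast, and
turbidity generated with a steep northern dispersion (2.30) and a
shallow southern one (0.77). Two design points matter. Distances are
over-water (shortest paths on the unmasked lattice, routed around the
headlands): with straight-line distances through land, the shallow
southern decay dominates both coasts and the northern dispersion
parameter collapses to its prior. And the north-coast loadings must be
large enough that each coast's near-shore pixels are dominated by their
own plumes — which is also the physically sensible configuration for a
coastline whose turbid side is the deforested one. On this fixture the
per-coast-dispersion model recovers both generating magnitudes and wins
DIC and hold-out RMSE against the single-dispersion model.

## Benthic verification

Predicted turbidity is extracted at survey sites (containing cell, with
a one-cell nearest-unmasked fallback) and regressed against percent
cover with family-per-habitat models: zero-inflated log-linear for
silt, a linear model on logit-transformed proportions for
sediment-sensitive coral, and zero-inflated logit for algae.
Zero-inflated families are fitted by maximum likelihood in two
independent parts (Bernoulli presence; conditional positive part), and
the slope, p-value (threshold 0.05, no multiple-testing correction
across the three habitats) and 95% confidence band come from the
continuous part. Proportions are mapped through the
$(p(n-1)+0.5)/n$ adjustment before the logit so 0 and 1 stay finite;
this slightly attenuates slopes when covers approach the boundary,
which is visible in round-trip tests if generating curves run very
close to 0% cover. The survey fixture generator draws covers from the
same families given local turbidity, providing a known-truth round trip
for the fitting machinery.

## Numerical choices and degenerate inputs

* Distances are floored at 0.5 km everywhere (simulator, distance
  matrices), shared with the kernel's singularity guard.
* Land-use fractions must sum to 1 within $10^{-9}$; constant
  observation vectors, all-zero loadings, empty catchment sets, and
  misaligned flag grids raise immediately rather than propagating.
* Min-rescaling is intentionally not idempotent; fields carry a
  `rescaled` flag and re-application errors.
* Mouth grouping uses `hclust(method = "single")` cut at the threshold:
  exactly the transitive closure of the within-5-km graph, so chains of
  mouths merge. The threshold is applied to straight-line distances.
* Block resampling averages unmasked member cells (unbiased for
  regional means); blocks with no unmasked member stay masked.
* "Adjacent to reef" means 8-connected neighbours.
* Problem sizes in the tests and the acceptance script — 25-replicate
  batches, 2 × 4000-iteration chains, three-setting sweeps — were
  chosen as the smallest sizes at which convergence is routine and the
  recovery metrics resolve sub-percent bias.

## Known limitations

* The attribution inherits the power kernel's isotropy; systematic
  alongshore transport will be absorbed into (and bias) per-coast
  dispersion parameters.
* With few source groups, the deviation precision $\tau_\nu$ is weakly
  identified; its vague gamma prior admits both strong-shrinkage and
  loose regimes, which is the main driver of replicate-to-replicate
  variability in contribution-share estimates.
* DIC and predictive loss are relative measures within a dataset; their
  magnitudes are not comparable across preprocessing choices (they
  change with rescaling, resampling and hold-out fraction).
* The catchment model has no stream-bank erosion, sediment storage, or
  sub-catchment resolution; loadings are wet-season totals, so the
  model applies to time-integrated exposure rather than event plumes
  unless refitted at event scale.
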