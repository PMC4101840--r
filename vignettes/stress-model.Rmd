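---
title: "Mutational stress, packing density and site-specific evolutionary rates"
author: "StressENM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational stress, packing density and site-specific evolutionary rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StressENM)
```

## The question

Protein sites do not evolve at a uniform rate: buried, densely packed
sites accumulate amino-acid substitutions far more slowly than exposed
ones, and the best single structural predictor of a site's rate is its
local packing density (LPD). Why should packing density, a purely
geometric quantity, control the substitution rate? Two explanations
compete:

* **Flexibility model** (empirical): flexible sites accommodate mutations
  more easily, so the rate increases linearly with the site's dynamical
  flexibility, measured by its mean square fluctuation (MSF). Packing
  density would matter only as a proxy for flexibility, since MSF is
  roughly proportional to 1/LPD.
* **Stress model** (mechanistic): a mutation perturbs the protein's
  energy landscape; selection favours mutants that still populate the
  native, active conformation. The expected acceptance probability of a
  random mutation at a site then decreases linearly with the *mean local
  mutational stress* (MLmS) of that site — and MLmS turns out to be
  exactly proportional to LPD.

This package implements both models on top of coarse-grained elastic
network models (ENMs) and provides the statistical machinery (AIC,
Akaike weights, Pearson and partial correlations, binned profiles) to
compare them, together with synthetic structure generators so the whole
analysis runs end to end without any external data.

## The elastic network layer

A protein chain is reduced to its N C-alpha positions
$\mathbf r_1,\dots,\mathbf r_N$. Springs connect pairs of sites and are
relaxed at the native conformation $\mathbf r^0$, so the potential is

$$V(\mathbf r) = \tfrac12 \sum_{i<j} k_{ij}\,(d_{ij} - d^0_{ij})^2 ,$$

with $d_{ij}$ the instantaneous and $d^0_{ij}$ the native inter-site
distance. Two standard spring rules are provided:

* **pfANM** (`buildPfANM()`): $k_{ij} = 1/(d^0_{ij})^2$ for every pair —
  no cutoff, no free parameter;
* **ANM** (`buildANM()`): $k_{ij} = 1$ for $d^0_{ij} \le R_{cut}$ and 0
  beyond, with the boundary inclusive. The default cutoff is 13 Å, a
  mid-range choice of the usual 10–18 Å window.

Thermal fluctuations follow from the quadratic expansion of $V$: the
Hessian $\mathbf H$ is assembled analytically (`buildHessian()`;
off-diagonal block $-k_{ij}/(d^0_{ij})^2\, \mathbf d_{ij}\mathbf
d_{ij}^T$), and its Moore–Penrose pseudo-inverse gives the covariance
$\mathbf C$ (`covarianceFromHessian()`). A site's flexibility is

$$\mathrm{MSF}_i = \mathrm{Tr}\,\mathbf C_{ii} / \beta .$$

With the site stiffness $k_i = \sum_{j\ne i} k_{ij}$, the single-site
approximation $\mathrm{MSF}_i \approx 3/(2\beta k_i)$ links flexibility
to reciprocal packing density; it is only approximate, and the package
treats it as such (it is validated as a correlation, never used in place
of the exact MSF).

## Mutations as random spring perturbations

A mutation at site $i$ perturbs the rest length of each spring incident
to $i$: $d^0_{ij} \to d^0_{ij} + \delta_{ij}$, with the $\delta_{ij}$
independent, zero-mean, variance $\alpha^2$. Holding the mutant at the
wild-type native conformation, each perturbed spring stores
$\tfrac12 k_{ij}\delta_{ij}^2$, so the expected stored energy — the mean
local mutational stress — is the exact identity

$$\mathrm{MLmS}_i = \tfrac12 \alpha^2 k_i ,$$

independent of the shape of the perturbation distribution
(`mlmsAnalytic()`; the Monte-Carlo estimator `mlmsMonteCarlo()` checks
this with both Gaussian and uniform perturbations). Selection enters
through the Boltzmann weight of the native conformation: the expected
acceptance probability of a mutation at site $i$ is
$\omega_i = \langle e^{-\beta\,\Delta V}\rangle$, which linearizes under
weak selection to

$$\omega_i \simeq 1 - \beta\,\mathrm{MLmS}_i .$$

For Gaussian perturbations the exact average has the closed form
$\prod_j (1+\beta\alpha^2 k_{ij})^{-1/2}$
(`acceptanceRateClosedForm()`), which the package keeps alongside the
linearized form: by Jensen's inequality the exact rate always lies above
the linearization, and the gap is the known breakdown of the
weak-selection approximation at strongly packed sites. No resolution of
that residual nonlinearity is imposed; both routes are exposed.

Because $k_i$ *is* the weighted contact number (WCN) under the pfANM
rule and the contact number (CN) under the ANM rule, z-normalizing
within a protein gives the exact chain of identities

$$\widetilde{\mathrm{MLmS}}_i = \tilde k_i = \widetilde{\mathrm{LPD}}_i ,$$

while $\widetilde{\mathrm{MSF}}_i \approx \widetilde{1/k_i}$ only
approximately. This is the mechanistic explanation the package is built
around: stress, not flexibility, carries the packing-density signal.

## Relative values and the two fitted models

All per-site quantities are compared as within-protein z-scores using
the population standard deviation,
$\tilde x = (x - \langle x\rangle)/\sqrt{\langle x^2\rangle - \langle
x\rangle^2}$ (`znorm()`). This removes the unit choices ($\beta$,
$\alpha^2$, any global spring-constant scale) from every downstream
result — an invariance the test suite asserts directly. The population
(rather than sample) SD matches the convention of the supplementary
site-table schema the package reads and writes.

The two models are then simple linear regressions of the z-scored rate
on one z-scored predictor per protein (or pooled over proteins):

* stress: $\tilde\omega_i = a + b\,\widetilde{\mathrm{MLmS}}_i$ (expected $b<0$),
* flexibility: $\tilde\omega_i = a + b\,\widetilde{\mathrm{MSF}}_i$
  (expected $b>0$; a B-factor variant is available when the structure
  provides B-factors).

Goodness of fit uses the Gaussian maximum-likelihood AIC with $k = 3$
parameters (intercept, slope, error variance) including the $2\pi$
constant — the convention of `stats::AIC` for `lm` — and model pairs are
weighted by $w \propto e^{-\Delta\mathrm{AIC}/2}$. Association is
reported as Pearson correlations and as first-order partial correlations
(each model's predictor controlling the other's), which is where the two
models separate most sharply: when rates are generated by stress, the
rate–MSF partial correlation controlling MLmS nearly vanishes.

Binned profiles (`binnedProfile()`) summarize the shape of the
rate–predictor relationships: sites are split into 20 equal-count bins
by the predictor (remainder sites go one-per-bin to the leading bins,
ties keep original order) and per-bin means are reported with a 99%
normal-approximation confidence half-width ($2.5758\,\mathrm{sd}/\sqrt
n$). A quadratic-term F-test on the bin means
(`profileCurvatureTest()`) operationalizes "visibly nonlinear": because
rates are (approximately) linear in MLmS and MSF ≈ 1/MLmS, the rate–MSF
profile must be curved while the rate–MLmS profile is not.

## What the synthetic generator emulates

Real structures are read from PDB files (`readCaTrace()`: CA atoms only,
first model, highest-occupancy altLoc, residues without CA skipped).
For self-contained analysis the package generates:

* `makeHelixTrace(n)` — an ideal alpha helix (radius 2.3 Å, rise 1.5 Å,
  100° per residue, giving ~3.8 Å virtual bonds); a deterministic,
  hand-checkable geometry.
* `makeGlobuleTrace(n, seed)` — a self-avoiding chain with exact 3.8 Å
  bonds, minimum inter-site distance 3.5 Å, confined to a sphere of
  radius $3.0\,n^{1/3}$ Å so the mean density matches folded globular
  proteins, regrown until the 13 Å network is connected. This emulates
  the packing-density *spectrum* of a folded monomeric enzyme — a dense
  interior and a looser surface — which is the only structural feature
  the stress/flexibility comparison depends on.

The generator does **not** emulate secondary-structure regularity,
side-chain packing anisotropy, multi-domain architecture, or crystal
B-factor artefacts. Passing tests on these fixtures therefore
demonstrate the internal consistency of the machinery and the
qualitative behaviour of the two models under a known generative
process; they do not by themselves certify effect sizes on real
proteins, which require real structures and real rate inferences as
inputs.

`makeStressStudy()` defines the package's reference synthetic study: 20
globules of 120 sites each (a small enzyme's worth of sites, large
enough for stable per-protein fits while keeping a full study under a
minute), with rates generated as $-\widetilde{\mathrm{MLmS}} +
\varepsilon$, $\varepsilon \sim N(0, 0.8^2)$ on the z scale. The noise
SD of 0.8 yields site-level rate–predictor correlations around $-0.78$,
deliberately in the regime of strong-but-noisy structural determination
reported for real enzyme datasets. A `generativeModel = "flexibility"`
switch produces the symmetric control (rates from MSF).

## Numerical choices

* **Units**: energies in kT ($\beta$ defaults to 1); $\alpha^2$ defaults
  to 1 Å². Both cancel from every z-scored result.
* **Zero modes**: eigenvalues at or below $10^{-8}\lambda_{max}$ are
  rigid-body modes; exactly six are required (three translations, three
  rotations) or the covariance step fails loudly — a disconnected ANM
  graph is an error, never silently inverted. Deliberately degenerate
  geometries (a two-site system has only five rigid modes) can be
  analysed via the `expectedZeroModes` argument.
* **Eigensolver**: dense symmetric eigendecomposition; intended for
  single-chain problems (N up to ~1500 sites on a desktop).
* **Boundary convention**: the ANM spring rule and CN both use
  $d \le R_{cut}$ inclusively; at 13 Å, exactly-boundary pairs are
  measure-zero in practice.
* **Monte-Carlo**: estimators take an explicit seed and restore the
  caller's RNG state, so seeded runs compose deterministically;
  the MC estimate of MLmS is validated against the analytic identity at
  four standard errors, and the MC acceptance rate against the Gaussian
  closed form.
* **Degenerate fits**: a perfect linear fit (residual sum of squares
  below $10^{-12}$) has an undefined Gaussian likelihood and is an
  error; constant columns are errors at the z-scoring step with the
  protein and column named.
* **Curvature replicates**: the curvature contrast (curved rate–MSF,
  straight rate–MLmS) is assessed per replicate *study* on the pooled
  2400-site profile. At single-protein size (120 sites) the quadratic
  F-test at $p<0.01$ has only ~70% power under the reference noise
  level, so the study — not the protein — is the natural replicate unit
  for this property.

## Worked example

```{r demo, eval = FALSE}
demo <- runDemo(seed = 1)
#> Synthetic study: 20 proteins x 120 sites (seed 1)
#>   stress model wins AIC in 20/20 proteins (pfANM)
#>   pooled: w(AIC)[stress] = 1.0000, r(rate, MLmS) = -0.768, r(rate, MSF) = 0.721
#>   pooled partial r: stress|flex = -0.384, flex|stress = 0.045
```

The signature result pattern: both predictors correlate strongly with
the rates, but the AIC decisively prefers the stress model, and once
stress is controlled for, almost no rate–flexibility correlation
remains — flexibility's apparent explanatory power is inherited from its
approximate reciprocal relationship with stress.

## Known limitations

* Rates are consumed as given (e.g. Rate4Site output); no phylogenetic
  inference is performed, and rate-estimation bias propagates untouched.
* Springs are C-alpha-level and sequence-agnostic: no amino-acid-specific
  mutation matrices, no epistasis, no explicit folded/unfolded
  concentration bookkeeping (its cancellation is assumed).
* The linearized acceptance rate can go negative for extreme stress;
  this is reported as-is (z-scoring removes the issue downstream), and
  the exact exponential route is available for exploring the residual
  nonlinearity.
* mmCIF files, non-protein polymers and multi-model ensembles beyond the
  first model are out of scope.
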