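---
title: "Quantifying cell decision-making errors from single-cell response distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell decision-making errors from single-cell response distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldecide)
library(ggplot2)
```

## The model

A cell reading its environment faces a binary hypothesis test. Take the
TNF--NF-kB pathway as the running example: the input is the TNF dose, the
readout is the nuclear NF-kB level `x` measured in single cells, and the cell
must effectively decide between

* H0 — the stimulus is low, responses distributed as `p(x | H0)`;
* H1 — the stimulus is high, responses distributed as `p(x | H1)`.

Because transduction noise (intrinsic reaction stochasticity plus extrinsic
cell-to-cell variability) spreads each conditional response distribution,
the two densities overlap and every decision rule makes mistakes:

* **false alarm** — deciding H1 when H0 is true, with probability `P_FA`
  equal to the H0 mass inside the decide-H1 region;
* **miss** — deciding H0 when H1 is true, with probability `P_M` equal to
  the H1 mass in the decide-H0 region;
* **overall error** `P_e = P(H0) P_FA + P(H1) P_M`.

The rule minimizing `P_e` decides H1 whenever
`P(H1) p(x | H1) > P(H0) p(x | H0)`; with equal priors this is the
maximum-likelihood decision. `celldecide` fits per-condition response models
from long-format single-cell tables, solves for the decision boundary, and
reports `P_FA`, `P_M`, `P_e` with full provenance.

## Gaussian treatment and the threshold quadratic

Per condition the response is modeled as `N(mu, sigma^2)`, fitted by
`fit_gaussian()` with the sample mean and the unbiased (n − 1) variance.
With the hundreds of cells per condition typical of these experiments the
biased and unbiased estimators agree far beyond the second decimal at which
error probabilities are usually read, so the choice does not affect
reported values; it is fixed for reproducibility.

Setting the prior-weighted log densities equal gives a quadratic in `x`
whose relevant root — the one strictly between the two means — is the
decision threshold returned by `ml_threshold()`. The error probabilities
then reduce to Gaussian tails through the Q function
(`q_gauss()`, the standard normal upper-tail probability):

```
P_FA = Q((threshold - mu0) / sigma0)
P_M  = Q((mu1 - threshold) / sigma1)
```

Numerical choices worth knowing:

* **Equal variances.** The quadratic coefficient vanishes; the linear
  equation is solved directly (midpoint of the means, shifted by
  `sigma^2 log(P(H0)/P(H1)) / (mu1 - mu0)`), avoiding catastrophic
  cancellation near `sigma0 = sigma1`.
* **Root selection and the exact region.** With unequal variances the
  quadratic can have two real roots and the true decide-H1 set can be an
  interval or the complement of one, not a half-line. The default
  `single_threshold` mode reproduces the conventional treatment (one
  threshold between the means, tails via the Q function).
  `decision_analysis(mode = "exact_region")` integrates the exact Bayes
  regions instead and is used automatically by the data pipeline when no
  between-means crossing exists (e.g. nearly identical conditions, where
  the answer is `P_e` near 1/2). For well-separated conditions the two
  modes differ only through far-tail mass and agree to the precision at
  which results are reported.
* **Ties.** A response exactly at the threshold decides H0, consistent
  with the strict inequality in the decision rule. The event has measure
  zero under the model but the convention matters for empirical data.
* **Verification tolerances.** The returned threshold satisfies the
  density-equality condition to 1e-9 relative; the test suite checks the
  closed-form tails against adaptive quadrature to 1e-8 and the threshold
  against an independent bisection oracle to 1e-6.

`error_vs_threshold()` evaluates the whole error curve on a grid, which is
how the optimality of the maximum-likelihood threshold is demonstrated and
tested.

```{r univariate}
tbl <- generate_dataset(paperlike_scenario())
early <- analyze_condition_pair(tbl, dose_low = 0.0021, dose_high = 8, time = 30)
late  <- analyze_condition_pair(tbl, dose_low = 0.0021, dose_high = 8, time = 240)
glance(early)
glance(late)
autoplot(early)
```

## Priors

Equal priors are the default everywhere: they encode the absence of a
priori knowledge about the input level, and make `P_e` the plain average of
`P_FA` and `P_M`. All functions accept `decision_priors(p_h0, p_h1)`;
the threshold then solves the prior-weighted density equality and the
likelihood-ratio cutoff `P(H0)/P(H1)` is exposed via
`likelihood_ratio_cutoff()`.

## Joint early/late decision

Measuring the same cell at an early and a late time point gives a paired
readout `(x, y)` modeled per hypothesis as a bivariate Gaussian with
correlation `rho` (`bivariate_model()`). The joint rule compares
prior-weighted joint densities; its boundary is a curve in the plane and
the error masses have no convenient closed form, so
`mc_error_probabilities()` estimates them by Monte-Carlo integration —
draw from the H0 model, count the fraction landing where the weighted H1
density wins (that is `P_FA`), and symmetrically for `P_M`.

Choices made here:

* The decision is implemented directly as a per-sample density comparison;
  the threshold curve is exposed only for plotting
  (`threshold_curve()`, `plot_threshold_curve()`). Extracting the curve and
  integrating against it would add discretization error for no benefit.
* The seed is a mandatory argument of `mc_settings()`; there is no hidden
  global random state, and a fixed seed reproduces estimates exactly.
* Default `n_samples = 1e6` per hypothesis puts the binomial standard
  error near 5e-4, comfortably inside the second decimal; estimates carry
  `sqrt(p(1-p)/n)` standard errors in the result.
* The correlation is resolved in order: user-supplied `rho`, else the
  Pearson correlation of per-cell paired data (`estimate_correlation()`),
  else an error asking for it. Marginals are always fitted from the full
  per-time slices, so a supplied `rho` works even when cell identities are
  not linked across time points. When the correlation can only come from
  an external source (e.g. a pathway simulator), `rho_sensitivity()`
  reports how the joint error responds across a grid of assumed values,
  rather than guessing one.

```{r joint}
joint <- joint_analysis(tbl, 0.0021, 8,
                        settings = mc_settings(seed = 11, n_samples = 2e5))
tidy(joint)
```

## Empirical (distribution-free) mode

When the Gaussian assumption is not wanted, thresholds and error
probabilities are read directly off the data. `build_histogram()`
normalizes a histogram (default binning: Freedman–Diaconis on the input
samples — the rule is recorded in the model so results are reproducible);
`empirical_threshold()` scans the union of bin edges for the prior-weighted
error minimum (ties resolved toward the lowest edge, disjoint supports
flagged); a threshold falling inside a bin splits the bin mass by linear
interpolation, which removes bin-width discontinuities from the error
curve. When raw samples are available the pipeline uses direct tail
fractions (`empirical_error_rates()`) instead of binned masses, avoiding
binning loss; histograms are for pre-binned input.

## The radar reference model

`radar_scenario()` implements the textbook problem this framework descends
from: detect a constant-amplitude signal `A` in `N` samples of Gaussian
noise. The optimal detector thresholds the sample mean at `A/2` and all
quantities are closed-form (`P_FA = Q(sqrt(N) threshold / sigma)`, etc.),
which makes the radar module an analytic oracle: the test suite checks it
against simulation (`radar_monte_carlo()`) and checks the general Gaussian
machinery against it at `N = 1`, where the two must agree to machine
precision.

## The synthetic data generator

`scenario_spec()` + `generate_dataset()` produce long-format single-cell
tables from declared per-condition Gaussian parameters, drawing each cell's
(early, late) pair from the implied bivariate Gaussian — deterministic
under the spec's seed. `paperlike_scenario()` is a packaged fixture whose
parameters are **synthetic**: they reproduce the qualitative structure of
published TNF--NF-kB response data (well-separated early distributions,
overlapping late ones, an A20-deficient variant with an upward-shifted and
broadened low-dose response, means saturating in dose), but not the
unpublished means and variances behind any measured dataset. Its numbers
must not be read as a reproduction of experimental results.

What the generator emulates: per-condition approximately-Gaussian response
levels, hundreds of cells per condition, two time points with
inter-time-point correlation, six doses, two genotypes. What it does not
emulate: non-Gaussian tails and skewness of real reporter distributions,
measurement noise distinct from biological noise, temporal trajectories
beyond two time points, and dose-dependent correlation structure. Tests
passing on this fixture therefore validate the decision machinery, not the
Gaussianity of any particular experimental system.

The deficient-cell analysis deliberately applies the wild-type threshold:
cells unaware of their own deficiency keep deciding with the boundary the
intact pathway would use, which is what inflates their false-alarm rate.
For the late time point the wild-type late-time optimal threshold is the
default borrowed boundary (parallel to the early-time convention); the
early-time threshold can be borrowed instead via `source_condition`.

```{r fixture}
ko_early <- analyze_condition_pair(
  tbl, 0.0021, 8, time = 30, genotype = "A20KO",
  policy = threshold_policy("fixed", source_condition = list(
    genotype = "WT", dose_low = 0.0021, dose_high = 8, time = 30)))
c(wild_type = early$p_fa, deficient = ko_early$p_fa)
autoplot(dose_sweep(tbl, reference_dose = 0.0021, time = 30))
```

## Problem sizes and test design

The packaged fixture uses 500 cells per condition — the "hundreds of
cells" regime the method targets; parameter-recovery checks use 1e4 cells
per condition so that sampling error (~1e-2 on fitted tail probabilities)
sits inside the 0.01 agreement band being tested; Monte-Carlo checks use
1e5–1e6 draws so that 3 binomial standard errors stay below a few 1e-3.
Closed forms are always validated against an independent numerical route:
bisection for thresholds, adaptive quadrature for univariate tails, dense
midpoint quadrature (with an external bivariate-normal density
implementation) for joint error masses.

## Limitations

* Two hypotheses only; multi-level dose discrimination is out of scope
  (doses are compared pairwise against a reference, as in `dose_sweep()`).
* Gaussian and histogram response models only; no kernel density
  estimation or copula-based joint models.
* Two time points in the joint analysis; the machinery would generalize
  but is deliberately not extended.
* Printed two-decimal error probabilities from measured single-cell
  datasets can only be reproduced from those datasets; the packaged
  fixture reproduces orderings and magnitudes, not specific published
  values. The MATLAB adapter (`read_measurements_mat()`) exists for users
  who have such an archive, and requires an explicit field mapping because
  `.mat` internal structure cannot be assumed.
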