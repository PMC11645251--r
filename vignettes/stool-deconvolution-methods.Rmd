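---
title: "Methods: deconvoluting stool microbiome compositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvoluting stool microbiome compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stooldemix)
```

## The model

Stool aggregates microbes shed along the whole gastrointestinal (GI) tract,
so a stool sample's composition is not the composition of any one GI
location. When reference samples from one location are available — here we
use the rectum, the usual biopsy site — the stool composition can be
decomposed. `stooldemix` models the counts `y_i` of `G` taxa in stool
sample `i` as

* `y_i | p_i ~ Multinomial(N_i, p_i)` with library size `N_i`,
* `p_ig = pi_i * p_r_g + (1 - pi_i) * p_o_g`, a per-sample convex
  combination of the rectum composition `p_r` and the "other GI locations"
  composition `p_o`,
* `pi_i ~ Beta(a1_i, a2_i)`, the latent fraction of sample `i`'s reads of
  rectal origin, reparameterized through its mean `mu_i = a1_i / (a1_i +
  a2_i)` and precision `phi_i = a1_i + a2_i` and linked to covariates by a
  beta regression: `logit(mu_i) = beta0 + x_i' beta` and `log(phi_i) =
  gamma0 + x_i' gamma`.

The reference samples are modeled as `y_j^(r) ~ Multinomial(N_j^(r), p_r)`
and `p_r` is estimated by the pooled proportions (`estimate_p_r()`), the
MLE under that model; it is then held fixed ("plugged in") while the stool
model is fitted. The scientific target is `p_o`, the composition that the
unobserved rest of the GI tract must have for the observed stool to arise
as a mixture, together with a global test of `H0: p_o = p_r`.

Conditioning on the beta law gives closed-form count moments
(`moments_y()`): the mean interpolates the two compositions at `E(pi)`, and
the variance adds to the multinomial term an `N_i^2 (p_r_g - p_o_g)^2
Var(pi_i)` component — between-sample heterogeneity that vanishes when the
two compositions agree, where the model collapses to a plain multinomial.

## Estimator 1: direct marginal maximum likelihood

`fit_demix1()` maximizes the marginal log-likelihood, a per-sample integral
over the latent `pi_i`, approximated with a fixed Gauss–Legendre rule and
assembled entirely in log space (log-gamma multinomial coefficients,
log-sum-exp over nodes), so large counts never overflow.

Two numerical choices matter:

* **Quadrature transform.** The beta density is singular at 0 and 1
  whenever a shape parameter is below 1 — the typical case at moderate
  precision (`phi ~ 1.2` under the default estimation design). A rule
  applied directly to `pi` integrates such factors poorly. By default each
  sample's integral is therefore transformed by its own beta CDF,
  `u = F(pi; a1_i, a2_i)`: the Gauss–Legendre rule then acts on the smooth
  multinomial factor alone and the beta factor integrates exactly. This
  makes the `p_r = p_o` reduction to the multinomial likelihood exact to
  machine precision, which the test suite asserts at `1e-10`. The plain
  affine-mapped rule is available as `scheme = "legendre"` for comparison.
  Even after the transform the integrand loses smoothness at the endpoints
  when a shape is below 1, so `marginal_loglik()` doubles its node count
  automatically in that regime, keeping its worst-case relative error below
  `1e-6` at 60 base nodes; the fitting engines use the base rule, whose
  residual objective error (order `1e-5`) sits well below the optimizer's
  stopping noise.
  The default of `n_quad = 30` nodes is validated by a saturation test:
  with a tight optimizer, doubling nodes from 20 to 40 to 80 moves the
  fitted composition by less than `1e-4`.
* **Softmax gauge.** `p_o` is optimized through the softmax map, which is
  invariant to adding a constant to its argument; the last coordinate is
  pinned at 0 to remove that flat direction from the simplex search.

The optimization itself is block-coordinate ascent, as the estimator is
usually described: Nelder–Mead over the softmax coordinates with link
coefficients held fixed, then Nelder–Mead over `(beta0, beta, gamma0,
gamma)` with the composition fixed, repeating until the objective changes
by at most `tol = 0.001` (checked after the coefficient block) or
`max_outer = 50` iterations. Each inner search runs to its own convergence
(relative tolerance `1e-6`, at most 2000 evaluations). If an inner
heuristic step would decrease the objective the previous block value is
kept, so the trace is monotone. Initialization: softmax coordinates from
the log pooled stool proportions (floored), coefficients at zero.

Mixture proportions inside logarithms are floored at a configurable
`floor = 1e-12` (renormalized), because a structural zero — a taxon absent
from the reference with numerically zero other-location mass but positive
stool counts — otherwise makes the objective `-Inf`. If that still happens
at initialization (flooring disabled), the fitter stops with an explicit
instruction to use the EM estimator.

## Estimator 2: Monte-Carlo EM

`fit_em()` works with the complete-data (joint) log-likelihood, which takes
logs term by term and is finite for any `pi` in the open interval, making
it the robust choice for extremely rare taxa or structural zeros. The
E-step draws `M = 50` values of each `pi_i` from its conditional given the
data and current parameters with a random-walk Metropolis–Hastings chain on
`logit(pi_i)` (independent chains across samples, advanced jointly;
proposal step 0.5, adapted multiplicatively toward a 35% acceptance rate
during a 200-iteration burn-in and then frozen so the retained, thinned
draws target the exact conditional). The M-step maximizes the Monte-Carlo
average of the joint log-likelihood over the softmax coordinates and link
coefficients jointly with one Nelder–Mead search (a blocked variant is
available). Convergence is declared when the L1 parameter change is at most
`tol = 1e-4` on two consecutive iterations — the doubled check guards
against a single lucky Monte-Carlo fluctuation — with a cap of `K = 30`
iterations. The whole fit is reproducible from one seed.

The per-iteration observed-data log-likelihood is recorded for diagnostics
only; with enough draws per E-step it is non-decreasing up to Monte-Carlo
noise, which the test suite checks on a small instance with `M = 500`.

## Global tests of `H0: p_o = p_r`

**Asymptotic test** (`test_asymptotic()`). The statistic is `T = ||p_hat_o
- p_hat_r||^2`. Under the null both estimated compositions obey a
multinomial central limit theorem with covariance `V(p) = diag(p) - p p'`
scaled by the group's total read count, so the null distribution of `T` can
be simulated: draw `v1, v2 ~ N_G(0, V(p_hat_r))` independently, form
deviations `v1 / sqrt(N_r_total)` and `v2 / sqrt(N_total)`, and take the
squared distance between them (`sample_null_T()`, default `B = 10000`
draws). The p-value is the add-one Monte-Carlo estimate, never below
`1/(1+B)`. The square-root scaling is required for the deviations to match
the multinomial variance of estimated proportions; an `"over_n"` variant
(deviations divided by the totals themselves) is provided for comparison
and demonstrably fails a direct-simulation check of the null — its draws
shrink like `1/N^2` while the statistic's real null scale is `1/N`.

**A calibration caveat, stated plainly.** The simulated null assumes
`p_hat_o` behaves like the multinomial MLE (the pooled stool proportions)
under `H0`. It does not. When `p_r = p_o` the data carry no information
about the latent mixing proportion: any `(mu, p_o)` pair on the ridge
`mu * p_hat_r + (1 - mu) * p_o = pooled stool proportions` fits equally
well, and a converged maximizer lands wherever its initialization put it —
near `mu = 0.5` with the default coefficient initialization — giving
`p_hat_o - p_hat_r = (p_bar - p_hat_r) / (1 - mu_hat)` and inflating `T` by
roughly `1/(1 - mu_hat)^2` (about four-fold) relative to the simulated
null. The type-I error of the asymptotic test at the 5% level is therefore
substantially above 5% under the null simulation design, and the package's
own calibration test documents this honestly rather than hiding it. Away
from the null the model is strongly identified (the latent proportions are
effectively observed through each sample's position along the line between
the two well-separated compositions), which is why estimation accuracy and
power are unaffected. Users who need a calibrated global test should use
the permutation test below, which is exact by exchangeability.

**Permutation test** (`test_permutation()`). Whole samples, with their
covariates, are pooled and randomly repartitioned into groups of the
original sizes; both compositions are re-estimated on each permuted split
(pooled proportions for the reference part, an EM fit for the stool part)
and the add-one p-value compares the observed statistic with the `B = 100`
permuted ones. Because each permutation repeats the whole EM, refits
default to a faster profile (`K = 10`, `M = 20`, burn-in 100); a failed
refit is redrawn with a message, up to a retry cap. Covariates must be
supplied for reference samples too — the reference model ignores them, but
they travel with samples into permuted stool groups.

## The synthetic-data generator

`sim_design()` fixes the generating configuration and `simulate_dataset()`
draws from it, bit-reproducibly from a seed. Two published designs are
built in:

* **Estimation design** (`mode = "uniform_pr"`): uniform rectum composition
  `1/G`; other-location composition from the evenly-spaced softmax
  construction (`make_true_po()`: `u_1..u_{G-1}` evenly spaced on `[-1, 1]`,
  `u_G` minus their sum — for `G = 5` this gives `(0.059, 0.116, 0.225,
  0.439, 0.161)`); link coefficients `(0.1, 0.1, 0.2, 0.1)`; one
  standard-normal covariate; `S = S_r = 100`.
* **Testing design** (`mode = "shifted_pr"`): the rectum composition is the
  softmax composition shifted by `+delta` on the first half of the taxa and
  `-delta` on the second half (`make_shifted_pr()`), so the total signal is
  `G * delta^2`; link coefficients `(0.1, 0.1, 0.7, 0.2)`; covariate from
  Normal(mean 10, sd 0.1) — we read the published "N(10, 0.1)" as a
  standard deviation of 0.1; with these links mean and precision are
  indistinguishable under either reading at this covariate spread. The
  half-split convention requires an even `G` when `delta > 0`. For `G = 2`
  the one-point "evenly spaced" grid is defined as the left endpoint `-1`.

The generator emulates exactly the stated statistical structure:
multinomial reference counts, beta-distributed mixing proportions linked to
one covariate, multinomial stool counts, equal library sizes within each
group. It deliberately does **not** emulate several features of real
sequencing data: zero inflation, overdispersion beyond the mixture
(e.g. Dirichlet-multinomial noise), varying library sizes, taxonomic
structure, or compositional artifacts of bioinformatic pipelines. Passing
tests therefore demonstrate correctness of the method under its own model,
not robustness to real-data violations of it. The latent mixing proportions
are returned for validation but are never written out as observed data.

For real tables, `rarefy()` (repeated subsampling without replacement,
averaged over `reps = 100` repetitions by default) and `aggregate_taxa()`
(summing counts to a higher rank, with an explicit unclassified bucket)
reproduce the usual preprocessing;
`rarefaction_depth_candidates()` reports the minimum and second-minimum
library sizes rather than silently choosing a depth, since depth selection
is data-dependent. Averaged rarefied counts are real-valued; pass
`round_counts = TRUE` (round-half-even) before multinomial fitting.

## Problem sizes used by the test suite

The suite re-runs the simulation studies at sizes chosen to exercise the
same operating characteristics at a fraction of the original replication:
the estimation study uses 30 replicates per `G = 5` cell and 10 per
`G = 10` cell at `S = S_r = 100` and depths 500/1000/5000; the type-I and
power studies use `G = 10`, `S = S_r = 50`, depth 3000, with 200 null
replicates and 100 per signal level, and a signal grid `delta in {0,
0.0014, 0.005}` placed to span the range between the test's baseline
rejection rate and saturation; permutation-null uniformity uses 50
replicates of a 15-sample, depth-300 design at `B = 50` with a minimal EM
profile. Monte-Carlo checks (moments, MH correctness, null-distribution
agreement) use fixed seeds and tolerances of three Monte-Carlo standard
errors or the stated Kolmogorov–Smirnov bounds.

## Known limitations

* The asymptotic test's null simulation is anti-conservative for the
  reasons above; treat its small p-values cautiously near the null and
  prefer the permutation test when calibration matters.
* `p_r` is treated as known once estimated; its sampling error enters the
  test through the simulated null but not the estimator of `p_o`.
* Only one reference location and a single "other" component are modeled;
  multi-location mixtures are out of scope.
* Nelder–Mead is a heuristic: reported optima carry stopping noise of
  order `1e-4` in the composition at default tolerances (an order below
  the statistical error at the supported designs).
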