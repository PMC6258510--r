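---
title: "TAGM models for protein localisation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAGM models for protein localisation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagmix)
```

This vignette is the package's own account of the statistical model it
implements, the choices that were genuinely open when writing it, and what
the test suite does and does not demonstrate.

## The model

A spatial proteomics experiment yields `N` protein profiles
`x_i` of length `D` (one abundance per collected fraction). A curated
marker set fixes the localisation of a labelled subset; the rest is
unlabelled. The T-augmented Gaussian mixture (TAGM) model places a
multivariate Gaussian `N(mu_k, Sigma_k)` on each of the `K` annotated
niches and one multivariate Student-t `T(kappa, M, V)` over the whole
profile space for proteins that no annotated niche describes well:

```
z_i ~ Categorical(pi)            # niche label
phi_i ~ Bernoulli(1 - epsilon)   # 1 = niche-derived, 0 = outlier
x_i | z_i = k, phi_i ~ N(mu_k, Sigma_k)^phi_i  T(kappa, M, V)^(1 - phi_i)
```

The t component is deliberately flat and heavy-tailed relative to the
niche Gaussians — it mimics a Gaussian with the global mean and half the
global covariance but with `kappa = 4` degrees of freedom — so dispersed,
multi-localising or unannotated proteins are absorbed there instead of
corrupting a niche estimate. For markers, `z_i` is clamped to the
annotation and `phi_i = 1`: curated markers are by definition unambiguous
single-niche proteins.

Conjugate priors complete the model: `pi ~ Dirichlet(beta)`,
`(mu_k, Sigma_k) ~ NIW(mu0, lambda0, nu0, S0)` shared across niches, and
`epsilon ~ Beta(u, v)`.

## Default hyperparameters and their rationale

`default_hyperparameters()` derives everything from the data. The t
parameters follow the model's stated convention: `kappa = 4`, `M` the
per-fraction mean over *all* proteins (labelled and unlabelled) and `V`
half the global empirical covariance. "Half the global variance" admits a
scalar, diagonal or full-matrix reading; the full `D x D` covariance is
used because fraction profiles are strongly correlated and a spherical
outlier component would misstate the directions in which dispersion
occurs. If halving leaves the matrix numerically non-positive-definite, a
ridge of `1e-6 * tr/D` is added.

The NIW constants follow standard mixture-model heuristics and are
deliberately weak: `mu0` the global mean, `lambda0 = 0.01` (the prior
mean is worth 1/100th of a protein), `nu0 = D + 2` (the smallest integer
degrees of freedom giving the inverse-Wishart a finite mean) and
`S0 = global covariance / K^(2/D)`, which scales prior niche volumes so
that `K` of them tile the data's spread. The Beta shapes `u = 2, v = 10`
weakly favour a minority outlier fraction (prior mean 1/6) while keeping
the posterior mode formula interior. All of these are declared defaults,
not estimates, and every one can be overridden through
`default_hyperparameters(..., name = value)`.

Sample covariances use the `(n - 1)` convention throughout, and every
density is evaluated in log space via Cholesky factors; profile
dimensions up to a few dozen fractions never underflow.

## MAP inference by EM

The E-step computes joint responsibilities over all `2K` outcomes
(niche x outlier route) with a log-sum-exp guard; the M-step is the exact
maximiser of the expected log-posterior — Beta and Dirichlet posterior
modes for `epsilon` and `pi`, and the joint NIW mode
`mu_hat_k = m_k`, `Sigma_hat_k = S_k / (nu_k + D + 2)` for each niche.
Because the M-step is an exact joint mode, the observed-data log-posterior
recorded in `posterior_trace` is non-decreasing; the suite verifies this
within `1e-8` on one hundred seeded datasets. Convergence is declared
when the trace changes by less than `tol` (default `1e-6`, with a 200
iteration cap, matching the reference analysis protocol).

EM needs a starting point the model does not dictate. The package uses a
deterministic one: `pi` and `epsilon` at their prior means and each
niche's `(mu_k, Sigma_k)` at the NIW posterior mode given its markers
only — equivalent to a single M-step on the labelled rows. This uses the
labelled data exactly as the model intends, makes every fit reproducible
without a seed, and on marker-anchored problems leaves little role for
random restarts, which are deliberately not provided.

## Collapsed Gibbs sampling

The sampler integrates out `pi` (Dirichlet-multinomial counts
`n_k^(-i) + beta_k`, where `n_k` counts the labels of *all* proteins,
whatever their `phi`) and `(mu_k, Sigma_k)` (NIW posterior predictive: a
Student-t with `nu_n - D + 1` degrees of freedom, location `m_n` and
scale `S_n (lambda_n + 1) / (lambda_n (nu_n - D + 1))` given the niche's
current members). `epsilon` is kept explicit and resampled from its Beta
full conditional after each sweep — equivalent in stationary distribution
to marginalising it, but it keeps the outlier weight directly
interpretable and its trace monitorable. Recorded localisation
probabilities are the *conditional* (Rao-Blackwellised) probabilities
computed during each sweep rather than sampled indicators, which lowers
Monte-Carlo variance at no cost.

Sufficient statistics (count, sum, outer-product sum per niche) are
updated incrementally as proteins move and rebuilt from scratch every
1000 sweeps as a numerical drift guard; an add-then-remove round trip
restores the predictive density to within `1e-12`. The sweep exists twice
by design: a pure-R reference (`collapsed_gibbs_sweep`) that is the
readable specification, and a compiled kernel used by
`run_tagm_chains()`. Both consume R's RNG stream identically, and the
suite checks they produce the same allocations draw for draw. On a tiny
two-protein instance the sampler's joint allocation frequencies are
checked against exhaustive enumeration of all 16 configurations weighted
by exact marginal likelihoods.

The multi-chain protocol mirrors standard practice: several chains with
sub-seeds derived deterministically from one master seed, burn-in
discarded, every `thin`-th sweep retained (with 15000/4000/10 this gives
1100 samples per chain), convergence monitored through the per-sweep
count of proteins allocated to known niches. `tagm_diagnostics()` computes
the Gelman-Rubin statistic across chains and a per-chain statistic
against the pooled rest, *flagging* suspect chains; chains are never
dropped silently — the caller chooses `keep` in `pool_chains()`, which can
also discard further early samples per chain before concatenation.
Summaries report Monte-Carlo means, 95% equi-tailed intervals (empirical
0.025/0.975 quantiles, R's linear-interpolation type 7 definition — fixed
because interval endpoints are part of the tested surface) and the
Monte-Carlo averaged Shannon entropy `H_i = mean_t( -sum_k p_ik(t) log
p_ik(t) )`, a per-protein uncertainty score in `[0, log K]`.

Classification applies one rule everywhere: a protein is assigned its
most probable outcome among the `K` niches *and* the outlier component,
but only when that probability exceeds the threshold (default 0.95);
otherwise it is reported unassigned. Stating the rule as argmax-then-gate
keeps the threshold-0 limit (everything gets its argmax) and the
outlier-call semantics consistent.

## Classifier assessment

`crossval_compare()` repeats a class-stratified 80/20 split of the marker
set (floor of the per-class count into training, remainder test, order
shuffled under the round seed), trains every requested method on the
training markers and scores probabilistic predictions on the withheld
markers with macro-F1 (argmax labels; zero-denominator classes contribute
F1 = 0) and the quadratic loss `Q2 = sum_i ||q_i - p_i||^2` — a sum, not
a mean, bounded by `2 N_test`. TAGM fits use the marker subset of the
quantitation matrix only (training rows labelled, test rows unlabelled):
the evaluation isolates what the markers teach each classifier and keeps
one round's fit independent of the unannotated proteome. TAGM's class
probability for the loss is `p(z = k | x) = a_ik + b_ik`, with the
outlier-route mass `b_ik = outlier_prob * pi_k`; for the MCMC variant the
posterior mean localisation is renormalised over the `K` niches, which
conditions on non-outlier status — appropriate because test markers are
curated non-outliers.

The KNN baseline implements Laplace-smoothed neighbour proportions
`p(z = k | x) = (N_k + alpha d_k C) / (K + alpha C)` with `alpha = 0.5`
(a Jeffreys-type pseudo-count) and `k` chosen by stratified 5-fold
cross-validation; as typeset the smoothing formula admits more than one
reading, and this is the unique one under which rows sum to one given
`sum_k N_k = K` and `sum_k d_k = 1`. The SVM baseline is consumed from
e1071 (probability outputs, internal 5-fold tuning of gamma and cost) and
degrades to a warning when unavailable. `compare_classifier_scores()`
provides two-sided pairwise t-tests with Benjamini-Hochberg correction
over the per-round scores, and `contingency_table()` the row-proportion
cross-classifier comparison.

## The synthetic-data generator

`generate_tagm_dataset()` draws from the generative model itself with
known ground truth: labels from `pi`, outlier indicators from
`Bernoulli(1 - epsilon)`, profiles from the niche Gaussians or the t
component. The study conditions used across the suite are the defaults a
practitioner would call realistic for a well-resolved experiment: a few
hundred to a few thousand proteins, 4-6 fractions, unit niche
covariances with means separated by 6 within-niche standard deviations,
`epsilon = 0.05`, and 20% of each niche's non-outlier proteins as
markers. Outliers are never selected as markers, matching the curated
nature of real marker lists. Profiles are real-valued and not constrained
non-negative: the model is defined on unconstrained profiles, and typical
inputs are already log-like transformed relative abundances.

What passing tests on such data show is that the inference machinery is
*correct* — monotone EM, exact collapsed conditionals, calibrated
bookkeeping — and that under the model's own assumptions both engines
recover labels, means and the outlier weight. What they do not show is
robustness to the ways real LOPIT data violate the model: non-Gaussian
niche shapes, correlated replicate structure, chimeric multi-localising
profiles that sit *between* niches rather than far from all of them, and
marker lists with curation errors. Conclusions about real data must rest
on the reported probabilities and entropies, not on the synthetic
recovery rates.

## Numerical choices and degenerate inputs

* Non-positive-definite covariance or scale matrices raise explicit
  degenerate-matrix errors at the density level.
* All responsibility and conditional-weight normalisations go through
  log-sum-exp; a protein whose every term underflows raises an error
  naming it (with finite log-densities this cannot occur).
* An empty niche in the M-step falls back to the prior-only NIW update;
  `beta < 1` with an empty niche would drive its weight negative and
  raises a parameter error instead.
* `nu0 = D + 2` guarantees positive predictive degrees of freedom
  (`nu0 - D + 1 = 3`) for empty niches.
* Ties in argmax classification resolve to the first (catalogue-order)
  class; ties in the KNN grid search resolve to the smallest `k`.
* Problem sizes in the tests — up to `N = 2000, D = 6, K = 4` for
  recovery, 100 datasets of `N = 500` for monotonicity, 50000 sweeps for
  the enumeration check — were chosen as the smallest scales at which the
  statistical assertions have comfortable Monte-Carlo margins.

## Known limitations

Single-niche allocation only: a protein resident in two compartments is
either absorbed by the outlier component or assigned with split
probabilities, but the model has no explicit multi-localisation state.
One `kappa` for the outlier component across the proteome. No
missing-value handling: profiles must be complete, as produced by the
upstream quantitation pipeline. The EM uses a single deterministic
initialisation rather than restarts, trading global-optimum guarantees
for reproducibility — on marker-anchored problems this is rarely
limiting, but sparse marker sets may warrant comparing the MAP fit
against the MCMC posterior, which does not depend on an initial point.
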