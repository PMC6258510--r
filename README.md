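# tagmix

Probabilistic assignment of proteins to sub-cellular niches from
quantitative fractionation profiles, using a **T-augmented Gaussian
mixture (TAGM) model**.

## The problem

Spatial proteomics experiments (LOPIT, hyperLOPIT, organellar maps)
separate cell content along a density gradient and quantify each protein
across `D` fractions, producing an `N x D` abundance matrix in which
proteins resident in the same organelle share a characteristic profile. A
curated subset of proteins — *markers* — has known localisation; the task
is to assign the remaining proteins to one of the `K` annotated niches,
with calibrated uncertainty, while recognising that many proteins
(multi-localising, or from uncharacterised compartments) fit no annotated
niche at all.

## The model

Each niche `k` is a multivariate Gaussian over profiles,
`x_i | z_i = k, phi_i = 1 ~ N(mu_k, Sigma_k)`, and a single heavy-tailed
multivariate Student-t component `T(kappa, M, V)` (with `kappa = 4`, `M`
the global mean and `V` half the global covariance) captures **outlier**
proteins (`phi_i = 0`, prior probability `epsilon`). Priors are conjugate:
Dirichlet(`beta`) on the mixture weights `pi`, normal-inverse-Wishart
(`mu0, lambda0, nu0, S0`) on each `(mu_k, Sigma_k)` and Beta(`u, v`) on
`epsilon`. Two inference engines share this model:

* **TAGM-MAP** — expectation-maximisation to the joint posterior mode;
  the MAP estimates are plugged into the allocation formula
  `p(z_i = k, phi_i = 1 | x_i) ∝ pi_k (1 - epsilon) f(x_i | mu_k, Sigma_k)`
  (and its outlier counterpart) to obtain per-protein localisation
  probabilities.
* **TAGM-MCMC** — a collapsed Gibbs sampler over `(z_i, phi_i)` with
  `pi` and `(mu_k, Sigma_k)` marginalised analytically (Dirichlet-
  multinomial counts and NIW posterior-predictive Student-t densities)
  and `epsilon` resampled from its Beta full conditional. Multiple chains,
  Gelman-Rubin diagnostics, 95% equi-tailed credible intervals and
  Monte-Carlo averaged Shannon entropies quantify uncertainty
  proteome-wide.

A classifier-assessment harness (repeated class-stratified 80/20 marker
splits, macro-F1, quadratic loss `Q2 = sum_i ||q_i - p_i||^2`, a
Laplace-smoothed probabilistic KNN and an optional SVM baseline) and a
generator for synthetic datasets drawn from the generative model round out
the package.

## Worked example

```r
library(tagmix)

means   <- separated_means(K = 4, D = 6, separation = 6, seed = 1)
sim     <- generate_tagm_dataset(n = 1000, means = means, epsilon = 0.05, seed = 2)
markers <- make_marker_annotation(sim, marker_fraction = 0.2, seed = 3)

fit <- fit_tagm_map(sim$expression, markers)
fit
#> TAGM-MAP fit: 1000 proteins, 4 niches
#>   iterations: 7 (converged)
#>   epsilon-hat: 0.06431

round(head(cbind(fit$localisation, outlier = fit$outlier_prob), 4), 4)
#>              class_1 class_2 class_3 class_4 outlier
#> protein_0001       0  0.9999       0  0.0000   1e-04
#> protein_0002       0  0.0000       0  0.9999   1e-04
#> protein_0003       0  0.0000       0  1.0000   0e+00
#> protein_0004       0  1.0000       0  0.0000   0e+00

table(tagm_classify(fit, threshold = 0.95))
#>    class_1    class_2    class_3    class_4    outlier unassigned
#>        252        247        223        213         61          4
```

Each row of `fit$localisation` plus the outlier probability sums to one;
`tagm_classify` reports a niche (or the outlier component) only when its
posterior probability exceeds the threshold, leaving ambiguous proteins
unassigned. The generating outlier fraction was 0.05 and the posterior
mode lands close by (0.064 with a Beta(2, 10) prior).

The fully Bayesian analysis adds interval estimates and entropies:

```r
ch <- run_tagm_chains(sim$expression, markers,
                      settings = mcmc_settings(n_chains = 4, n_iter = 1000,
                                               burn_in = 200, thin = 5, seed = 4))
tagm_diagnostics(ch)$rhat
#> [1] 0.9998                     # < 1.1: chains agree
summ <- summarize_posterior(pool_chains(ch))
round(head(cbind(summ$mean_localisation, outlier = summ$outlier_prob,
                 shannon = summ$shannon), 3), 4)
#>              class_1 class_2 class_3 class_4 outlier shannon
#> protein_0001  0.0000  0.9998       0  0.0000   2e-04   2e-04
#> protein_0002  0.0000  0.0000       0  0.9999   1e-04   1e-04
#> protein_0005  0.9992  0.0000       0  0.0000   8e-04   8e-04
```

A protein with near-zero Shannon entropy is confidently placed; larger
entropies (up to `log K`) flag proteins whose allocation is genuinely
uncertain, which no single hard assignment would reveal.

A thin command-line interface wraps the same functions
(`simulate`, `fit-map`, `fit-mcmc`, `assess`, `compare`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tagm.R", package = "tagmix"))')
Rscript $CLI fit-map --quant quantitation.tsv --markers markers.tsv --out results/
```

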