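---
title: "Annotation-informed Bayesian variance components for brain-wide association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-informed Bayesian variance components for brain-wide association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Brain-wide association studies regress a behavioral phenotype on tens of
thousands of imaging-derived features — here, Fisher-z transformed
functional-connectivity edges between cortical parcels — measured on far
fewer participants than there are features. Individual edge effects are tiny
and widely distributed, so thresholding single-feature associations gives a
biased picture. The variance-components approach instead asks two questions
jointly:

1. What fraction of phenotype variance (h², the "heritability" analogue for
   imaging features) do *all* features explain together?
2. Do features carrying a given *annotation* (for example, both endpoints in
   the Default Mode Network) explain systematically more variance per
   feature than the rest?

## The model

With standardized phenotype $Y$ ($n$ participants) and standardized feature
matrix $X$ ($n \times B$, $B \gg n$),

$$
Y = X\beta + \epsilon, \qquad
\epsilon \sim N(0, (1 - h^2) I_n), \qquad
\beta \sim N(0,\; h^2 \Psi),
$$

where $\Psi$ is diagonal with entries

$$
\Psi_{kk} \;=\; \frac{\exp(Z_k^\top \alpha)}{\sum_{j=1}^{B} \exp(Z_j^\top \alpha)} ,
$$

a softmax over per-feature annotation scores: $Z$ is the $B \times M$
annotation matrix and $\alpha$ the $M$ annotation weights. The entries of
$\Psi$ are positive and sum to one, so $h^2$ retains its interpretation as
the total fraction of variance explained while $\Psi$ allocates it across
features. At $\alpha = 0$ the allocation is uniform, $\Psi = I/B$, and the
model collapses to the classical homoscedastic (GCTA-style) variance
component. $\exp(\alpha_m)$ is the per-feature *enrichment ratio*: how many
times more variance an annotated feature explains than an unannotated one,
a priori. Priors complete the model: $h^2 \sim \mathrm{Beta}(a, d)$
(uniform at $a = d = 1$, the default) and
$\alpha \sim N(0, \sigma_\alpha^2 I)$.

## Why the default $\sigma_\alpha^2$ is 1, not huge

$\alpha$ lives on the log-enrichment scale, where reported within-network
enrichments are a few tenths (e.g. $\alpha = 0.19$, a 1.21-fold ratio).
A unit prior variance already places 95% of its mass on enrichment ratios
between roughly 1/7 and 7 — diffuse for any plausible effect.

Choosing an "uninformative" value such as $\sigma_\alpha^2 = 100$ has a
pathological consequence in the $B \gg n$ regime: at moderate sample sizes
the marginal likelihood carries only a few nats of information about
$\alpha$, so weights wander to $\pm 15$ and beyond, the softmax concentrates
essentially all prior variance on a single annotation group, and — because a
badly misallocated $\Psi$ fits best with a small total variance share — the
joint posterior drags $h^2$ far below the truth. In pilot runs at
$n = 600, B = 3000$ the $h^2$ posterior mean fell from ${\sim}0.5$ (unit
prior variance) to ${\sim}0.18$ (variance 100) against a generating value of
0.6, and per-feature credible intervals for $\beta$ undercovered. Both
hyperparameters remain user-settable via `prior_spec()`.

## Inference: a collapsed sampler

Because $\beta$ has $B$ dimensions but the data live in $n$, all posterior
computation goes through the $n \times n$ marginal covariance

$$
V \;=\; h^2\, X \Psi X^\top + (1 - h^2) I_n ,
$$

with $\beta$ integrated out. `run_mcmc()` alternates:

* **$\alpha$ block** — a joint Gaussian random-walk Metropolis proposal on
  all $M$ weights, accepted against marginal likelihood × prior. A joint
  block (rather than componentwise sweeps) is used deliberately: each
  proposal costs one Cholesky factorization of $V$, so componentwise updates
  would multiply the per-iteration cost by $M$ for little mixing gain at the
  annotation counts this package targets ($M \le$ a few dozen,
  single-annotation models in typical applications).
* **$h^2$ block** — random-walk Metropolis on $\mathrm{logit}(h^2)$ with the
  Jacobian correction. Proposals outside $(10^{-8}, 1 - 10^{-8})$ are
  rejected, not clamped, keeping the stationary distribution exact.
* **$\beta$ draw** — at every *recorded* iteration, an exact draw from the
  conditional posterior
  $N\!\big(\Sigma X^\top Y/(1-h^2),\, \Sigma\big)$,
  $\Sigma = [X^\top X/(1-h^2) + (h^2\Psi)^{-1}]^{-1}$, without ever forming
  a $B \times B$ matrix: a prior draw $u \sim N(0, h^2\Psi)$ and noise draw
  $\delta \sim N(0, (1-h^2)I_n)$ are corrected through one $n \times n$
  solve $V w = Y - (Xu + \delta)$, giving
  $\beta = u + h^2 \Psi X^\top w$ (cost $O(n^2 B)$). Because the chain is
  collapsed, $\beta$ never feeds back, and drawing it only at kept
  iterations changes nothing about the stationary distribution. The realized
  variance explained $\hat R^2 = \mathrm{var}(X\beta)/\mathrm{var}(Y)$ is
  recorded alongside.

Two computational devices make repeated likelihood evaluation cheap:

* **Annotation-group caching.** Binary annotation matrices have few unique
  rows, and $\Psi$ is constant within each unique profile, so
  $X \Psi X^\top = \sum_g w_g(\alpha) K_g$ with per-group Gram matrices
  $K_g$ precomputed once. An $\alpha$ proposal then costs
  $O(G n^2)$ plus one Cholesky, independent of $B$. Continuous annotations
  fall back to rescaling $X$ at each evaluation.
* **Eigen-decomposition for the homoscedastic model.** With no annotations,
  $K = XX^\top / B$ is fixed; one symmetric eigendecomposition per fit makes
  every $h^2$ update $O(n)$.

Proposal scales adapt during burn-in only (Robbins–Monro on the acceptance
probability, targets 25% for the $\alpha$ block and 40% for scalar $h^2$)
and are frozen afterwards, so the post-burn-in chain is a genuine Markov
chain. Chains are independent with per-chain seeds `seed + chain - 1`.
Reported summaries are medians and equal-tailed 95% percentile intervals of
the draws pooled ("intermixed") across chains; percentiles interpolate
between order statistics (R type 7), recorded in the summary metadata.

The default schedule (10,000 iterations, 3,000 burn-in, thinning 10, six
chains) mirrors a production analysis at $n \approx 5{,}000$,
$B \approx 60{,}000$. The simulation studies below use shorter, explicitly
stated schedules.

## Correctness harness

Three independent lines of evidence back the sampler, all in the test
suite:

* the collapsed likelihood agrees to $10^{-8}$ with an algebraically
  independent $B$-side (Woodbury) evaluation, and the conditional $\beta$
  draw matches the dense-formula posterior mean and covariance on small
  instances;
* a deliberately *uncollapsed* sampler (Metropolis on $h^2, \alpha$ given
  $\beta$, exact $\beta$ Gibbs draws) targets the same posterior and agrees
  with the collapsed chain within Monte Carlo error on a small instance;
* simulation-based calibration: over replicates with parameters drawn from
  the prior, the rank of the generating value among posterior draws is
  uniform (`simulation_based_calibration()`); a negative control that
  sharpens the likelihood (`likelihood_power > 1`) is reliably rejected.
  Ranks are computed from heavily thinned draws; residual autocorrelation
  makes the chi-square test slightly anticonservative, hence the strict
  p > 0.01 criterion.

## What the synthetic-data generator emulates

`simulate_dataset()` reproduces the structure of a connectome-wide design:

* a standardized $n \times B$ design, optionally column-correlated
  (equicorrelated, or blocks of adjacent features sharing correlation 0.5 in
  blocks of 10 — a stand-in for edges incident to a common parcel);
* $M = 10$ disjoint binary annotations, each covering 8% of features, with
  annotated features contiguous. One fifth of features carry no annotation.
  This departs from a fully covering partition on purpose: the softmax is
  invariant to adding a constant to all scores, so when every feature is
  annotated the overall level of $\alpha$ is identified only by its prior;
  unannotated features anchor the level. Real connectome annotation sets
  behave the same way (most edges fall in no named network);
* generating weights $\alpha_1 = -1.13$, $\alpha_2 = 0.38$ (a depleted and
  a mildly enriched annotation), the rest zero;
* effects drawn with the model's marginal variances $h^2 \Psi_{kk}$ but,
  optionally, AR(1) serial correlation $\rho^{|k - k'|}$ along the feature
  ordering — a controlled violation of the prior's independence assumption.
  The printed product form of that covariance is inconsistent at $k = k'$;
  the square-root form
  $h^2 \sqrt{\Psi_{kk}\Psi_{k'k'}}\, \rho^{|k-k'|}$ is used so the diagonal
  equals the prior variance exactly, and $\rho = 0$ recovers the model's own
  prior;
* phenotypes $Y = X\beta + \epsilon$ with noise variance $1 - h^2$,
  standardized after generation.

What it does *not* emulate: the long-range dependence structure of real
connectivity matrices (low-rank network structure, site and scanner
effects, non-Gaussian tails), head-motion artifacts, or annotation error.
Passing recovery tests on this generator demonstrates the estimator's
correctness under its stated assumptions and its robustness direction under
serial effect correlation — not performance on any particular cohort. In
particular the magnitude of the upward $h^2$ bias under large $\rho$ depends
strongly on the real design's correlation structure, so only its direction
(non-decreasing in $\rho$) is asserted.

## Experiment drivers and problem sizes

`run_grid_experiment()` scores parameter recovery over a $\rho \times h^2$
grid (posterior means, pooled and per-chain interval containment,
per-feature $\beta$ coverage, realized $\hat R^2$ against $\hat h^2$), and
`train_test_shrinkage_experiment()` measures the drop from in-sample
$\hat h^2$ to out-of-sample squared correlation
$\mathrm{cor}(X_{ts}\hat\beta_{tr}, Y_{ts})^2$ — the polyvertex-score
shrinkage expected from finite training data.

The package's own validation runs use desk-scale dimensions chosen to
preserve the design's aspect ratios: $n = 600, B = 3000$ (1:5
participant:feature ratio) for the acceptance script's grid, $n = 300,
B = 1500$ with ten chains per setting in the test suite, $n_{tr} = 1500,
n_{ts} = 300, B = 3000$ for the shrinkage experiment, and $n = 100, B = 200$
for calibration replicates. At these sizes the $\alpha$ likelihood is worth
only a few nats, so pooled posterior means of $\alpha$ are visibly shrunk
toward zero while their 95% intervals contain the generating values; h²
recovery and $\beta$ coverage (93–95% observed) are the sharper checks.

## Prediction

`polyvertex_score()` computes $X_{new}\hat\beta$ with features aligned
strictly by ID (positional alignment across cohorts is refused — the
classic cross-cohort bug), using the per-feature pooled posterior median of
$\beta$ by default (posterior mean via `estimate = "mean"`).
`incremental_r2()` reports the gain in (unadjusted) $R^2$ over covariates;
`out_of_sample_h2()` reports the squared correlation with a held-out
phenotype, which approaches $h^2$ only as the training sample grows.
Held-out cohorts are residualized on their own covariates and standardized
with their own moments by default, mirroring independent processing of an
external study; training-moment standardization is available via
`apply_standardization()`.

## Numerical choices and edge cases

* Softmax in log space with max subtraction; scores up to $\pm 700$ are
  safe.
* Marginal covariance formed explicitly as $n \times n$; no
  $B$-dimensional formulation is provided for $B < n$ (documented
  limitation — this package targets $B \gg n$).
* A failed Cholesky during sampling (degenerate proposal) counts as a
  rejection; at initialization it raises an error pointing at
  unstandardized input or duplicated participants.
* Fisher-z clips $|r| \ge 1 - 10^{-7}$ with a warning; exact $\pm 1$ would
  be infinite.
* Zero-variance columns are reported by feature ID at standardization.
* `store_beta` defaults to on when the draw array stays under ~0.5 GB; a
  running per-chain mean of $\beta$ is always kept, so the posterior-mean
  coefficient vector survives even when draws are not stored.
* Equal-tailed percentile intervals, not HPD — matching the reporting
  convention of published enrichment tables and their asymmetric intervals.
* No multiplicity correction across single-annotation models; the
  enrichment flag is based on the nominal 95% interval, as in the tables it
  mirrors.

## Known limitations

* Inference is Bayesian only; no REML/maximum-likelihood estimator.
* One variance component: no disjoint-partition multi-component extension.
* The $\alpha$ posterior is weakly informed unless $n$ is large; at small
  $n$ credible intervals are honest but wide, and posterior means shrink
  toward zero.
* No variational approximation; sampling cost is
  $O(n^2 B)$ setup plus $O(n^3)$ per iteration, about 50 ms per iteration
  at $n = 600$ on one core.
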