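# annovc

Annotation-informed Bayesian variance components for brain-wide association
analysis.

## What problem this solves

Connectome-wide studies regress a behavioral phenotype on tens of thousands
of imaging-derived features — Fisher-z functional-connectivity edges between
cortical parcels — measured on far fewer participants. Per-edge effects are
tiny and spread across the whole brain, so single-feature thresholding
misleads. `annovc` estimates, from subject-level data:

* **h²** — the fraction of phenotype variance explained jointly by *all*
  features under an additive model (the imaging analogue of SNP
  heritability), and
* **annotation enrichment** — whether features carrying an annotation (e.g.
  "both endpoints in the Default Mode Network") explain more variance per
  feature than the rest, quantified as an enrichment ratio exp(α).

It also turns a trained model into **polyvertex scores** `X_new β̂` for
out-of-sample or out-of-study prediction, with the incremental R² over
covariates.

## The model

With standardized `Y` (n participants) and standardized feature matrix `X`
(n × B, B ≫ n):

    Y = Xβ + ε,   ε ~ N(0, (1 − h²) Iₙ),   β ~ N(0, h² Ψ)

    Ψ = diag{ exp(Zₖᵀα) } / Σⱼ exp(Zⱼᵀα)

`Z` (B × M) holds per-feature annotations and `α` their weights. The
diagonal of Ψ is positive and sums to one, so h² stays the total variance
explained while Ψ allocates it; `α = 0` recovers the homoscedastic
GCTA-style model with prior variance h²/B per feature. Priors:
`h² ~ Beta(a, d)` (uniform by default) and `α ~ N(0, σα² I)`.

Inference is a collapsed Metropolis-within-Gibbs sampler on the n × n
marginal likelihood (β integrated out), with an exact O(n²B) conditional
draw of β at recorded iterations for reporting and for the realized
R̂² = var(Xβ)/var(Y). See the methods vignette
(`vignettes/annotation-informed-variance-components.Rmd`) for the sampler,
its correctness harness (dense-formula oracles, an independent uncollapsed
sampler, simulation-based calibration) and all numerical choices.

## Worked example

Simulate a study with 400 participants, 2,000 features and three disjoint
binary annotations (one enriched, one depleted, one null), fit three chains,
and inspect the posterior:

```r
library(annovc)

sim <- simulate_dataset(simulation_config(
  n = 400, B = 2000, M = 3, h2_true = 0.4,
  alpha_true = c(0.6, -0.6, 0), annotation_fractions = rep(0.15, 3),
  seed = 42))

fit <- run_mcmc(sim$data, prior_spec(),
                mcmc_config(n_iterations = 2000, n_burnin = 800, thin = 4,
                            n_chains = 3, seed = 1))
summarize_draws(fit)
#> Posterior summaries (900 pooled draws, 95% equal-tailed CIs)
#>  parameter median  lower upper   mean enrichment enrichment_lower
#>         h2  0.483  0.237 0.725  0.484         NA               NA
#>         R2  0.490  0.231 0.719  0.488         NA               NA
#>         A1  0.814 -0.487 2.065  0.805      2.256            0.614
#>         A2 -0.381 -2.149 1.071 -0.421      0.683            0.117
#>         A3 -0.913 -2.536 0.576 -0.929      0.401            0.079
#>  enrichment_upper         flag
#>                NA         <NA>
#>                NA         <NA>
#>             7.884 not-enriched
#>             2.919 not-enriched
#>             1.779 not-enriched
```

Reading this: the features jointly explain a posterior-median 48% of
phenotype variance (true value 0.4 inside the wide interval — at n = 400 the
h² posterior is honest but broad), the realized R̂² tracks h², and the three
annotation weights are ordered as generated (+0.6, −0.6, 0) though none is
flagged: at this sample size the annotation likelihood is weak, so the 95%
intervals straddle zero. The `enrichment` column is exp(α̂): annotation A1's
features explain a point estimate of ~2.3× as much variance per feature as
unannotated ones.

Prediction on a new cohort generated from the same effect vector:

```r
coef <- trained_coefficients(fit)   # per-feature pooled posterior medians
set.seed(99)
X_test <- simulate_design(3000, 2000)
Y_test <- simulate_outcome(X_test, sim$beta_true, 0.4)
out_of_sample_h2(X_test, Y_test, coef, feature_ids = coef$feature_ids)
#> [1] 0.034
```

The drop from ĥ² ≈ 0.48 in-sample to 0.034 out-of-sample is the expected
polyvertex-score shrinkage from estimating 2,000 coefficients on 400
participants (theory: roughly h²/(1 + B/(n·h²)) ≈ 0.03 for an uncorrelated
design); h² is the ceiling an infinitely large training sample would reach.

Building inputs from upstream artifacts: `build_edge_features()` vectorizes
per-participant node×node correlation matrices into Fisher-z edge features,
`build_annotation_matrix()` derives within-network annotations from a
node→network table, and `residualize()` / `standardize()` prepare `X` and
`Y` (covariate residualization, then column standardization with recorded
moments for held-out data).

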