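#' Simulation-based calibration of the sampler
#'
#' The standard correctness harness for an MCMC implementation: repeatedly
#' (i) draw (h2, alpha, beta) from the prior, (ii) generate a phenotype from
#' the model, (iii) run the sampler, and (iv) record the rank of the
#' generating value among the thinned posterior draws. A correct sampler
#' produces uniformly distributed ranks; uniformity is assessed per
#' parameter with a chi-square test over equal-width rank bins.
#'
#' Ranks are computed from thinned draws to tame autocorrelation; residual
#' dependence makes the chi-square slightly anticonservative, so calibration
#' is judged at a strict level (reject only below p = 0.01) rather than 0.05.
#'
#' @param prior an [prior_spec()]. Note the rank check validates the sampler
#'   against exactly this prior; a diffuse `sigma_alpha_sq` generates wildly
#'   heteroscedastic replicates, so calibration runs typically use a
#'   moderate value (e.g. 0.25).
#' @param n,B,M replicate dimensions (small by design).
#' @param annotation_fraction fraction of features annotated per annotation
#'   column (disjoint).
#' @param n_replicates number of prior-predictive replicates.
#' @param n_iterations,n_burnin,thin per-replicate chain schedule.
#' @param n_bins rank-histogram bins for the chi-square test.
#' @param likelihood_power passed to [mcmc_config()]; values other than 1
#'   deliberately break calibration and serve as a negative control.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return An object of class `annovc_sbc`: list with `ranks_h2`,
#'   `ranks_alpha` (replicates x M), `n_draws` (draws per replicate),
#'   `p_h2`, `p_alpha` (per-annotation chi-square p-values) and the settings.
#' @export
simulation_based_calibration <- function(prior = prior_spec(sigma_alpha_sq = 0.25),
                                         n = 100L, B = 200L, M = 1L,
                                         annotation_fraction = 0.3,
                                         n_replicates = 100L,
                                         n_iterations = 2100L,
                                         n_burnin = 100L, thin = 20L,
                                         n_bins = 10L,
                                         likelihood_power = 1,
                                         seed = 1L) {
  L <- (n_iterations - n_burnin) %/% thin
  ranks_h2 <- integer(n_replicates)
  ranks_alpha <- matrix(NA_integer_, n_replicates, M)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    X <- simulate_design(n, B, "iid")
    Z <- if (M > 0L) {
      simulate_annotations(B, M, rep(annotation_fraction, M))
    } else NULL
    h2_true <- stats::rbeta(1, prior$a, prior$d)
    alpha_true <- if (M > 0L) {
      stats::rnorm(M, 0, sqrt(prior$sigma_alpha_sq))
    } else numeric(0)
    psi <- if (M > 0L) compute_psi(Z, alpha_true) else rep(1 / B, B)
    beta_true <- stats::rnorm(B, 0, sqrt(h2_true * psi))
    Y <- drop(X %*% beta_true) +
      stats::rnorm(n, sd = sqrt(1 - h2_true))
    dat <- model_data(X, Y, Z, check_standardized = FALSE)
    draws <- run_mcmc(dat, prior, mcmc_config(
      n_iterations = n_iterations, n_burnin = n_burnin, thin = thin,
      n_chains = 1L, seed = seed + 100000L + r, store_beta = FALSE,
      likelihood_power = likelihood_power))
    ranks_h2[r] <- sum(draws$h2[1, ] < h2_true)
    for (m in seq_len(M)) {
      ranks_alpha[r, m] <- sum(draws$alpha[1, , m] < alpha_true[m])
    }
  }
  p_h2 <- .sbc_pvalue(ranks_h2, L, n_bins)
  p_alpha <- if (M > 0L) {
    vapply(seq_len(M), function(m) .sbc_pvalue(ranks_alpha[, m], L, n_bins),
           numeric(1))
  } else numeric(0)
  structure(
    list(ranks_h2 = ranks_h2, ranks_alpha = ranks_alpha, n_draws = L,
         p_h2 = p_h2, p_alpha = p_alpha, n_bins = n_bins,
         n_replicates = n_replicates,
         likelihood_power = likelihood_power),
    class = "annovc_sbc"
  )
}

# chi-square uniformity p-value for ranks in 0..L over n_bins bins
.sbc_pvalue <- function(ranks, L, n_bins) {
  breaks <- seq(-0.5, L + 0.5, length.out = n_bins + 1L)
  counts <- table(cut(ranks, breaks))
  suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
}

#' @export
print.annovc_sbc <- function(x, ...) {
  cat(sprintf(
    "annovc_sbc: %d replicates, %d draws each; p(h2) = %.3f%s\n",
    x$n_replicates, x$n_draws, x$p_h2,
    if (length(x$p_alpha)) {
      paste0(", p(alpha) = ",
             paste(sprintf("%.3f", x$p_alpha), collapse = ", "))
    } else ""))
  invisible(x)
}
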