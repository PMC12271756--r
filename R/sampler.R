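#' MCMC configuration
#'
#' Chain schedule and proposal settings for [run_mcmc()]. The defaults mirror
#' a production schedule for real-data analyses (10,000 iterations, 3,000
#' burn-in, thinning 10, 6 chains); simulation studies typically use shorter,
#' explicitly stated schedules.
#'
#' @param n_iterations total iterations per chain.
#' @param n_burnin iterations discarded from the start of each chain; must be
#'   smaller than `n_iterations`.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param n_chains number of independent chains; chain `c` uses random seed
#'   `seed + c - 1`.
#' @param seed base random seed.
#' @param proposal_sd_alpha initial scale of the joint Gaussian random-walk
#'   proposal on the annotation weights.
#' @param proposal_sd_h2 initial scale of the random walk on logit(h2).
#' @param adapt adapt proposal scales during burn-in (Robbins-Monro on the
#'   acceptance probability, targeting 25% for the alpha block and 40% for
#'   the scalar h2 block); scales are frozen at the end of burn-in.
#' @param store_beta keep every drawn effect vector (`chains x kept x B`
#'   array). Default `NULL` stores them when the array stays under ~0.5 GB;
#'   a running per-chain mean of beta is always accumulated.
#' @param likelihood_power exponent applied to the log marginal likelihood in
#'   the Metropolis ratios. The default 1 targets the exact posterior; other
#'   values temper (or sharpen) the likelihood and exist for sensitivity and
#'   calibration-harness checks.
#' @return An object of class `annovc_mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 10000L, n_burnin = 3000L, thin = 10L,
                        n_chains = 6L, seed = 1L,
                        proposal_sd_alpha = 0.3, proposal_sd_h2 = 0.6,
                        adapt = TRUE, store_beta = NULL,
                        likelihood_power = 1) {
  n_iterations <- as.integer(n_iterations)
  n_burnin <- as.integer(n_burnin)
  thin <- as.integer(thin)
  n_chains <- as.integer(n_chains)
  if (n_burnin < 0L || n_burnin >= n_iterations) {
    stop("'n_burnin' must satisfy 0 <= n_burnin < n_iterations")
  }
  if (thin < 1L) stop("'thin' must be >= 1")
  if (n_chains < 1L) stop("'n_chains' must be >= 1")
  if (proposal_sd_alpha <= 0 || proposal_sd_h2 <= 0) {
    stop("proposal scales must be positive")
  }
  structure(
    list(n_iterations = n_iterations, n_burnin = n_burnin, thin = thin,
         n_chains = n_chains, seed = as.integer(seed),
         proposal_sd_alpha = proposal_sd_alpha,
         proposal_sd_h2 = proposal_sd_h2, adapt = isTRUE(adapt),
         store_beta = store_beta, likelihood_power = likelihood_power),
    class = "annovc_mcmc_config"
  )
}

#' @export
print.annovc_mcmc_config <- function(x, ...) {
  cat(sprintf(
    "annovc_mcmc_config: %d iterations (%d burn-in, thin %d), %d chain(s), seed %d\n",
    x$n_iterations, x$n_burnin, x$thin, x$n_chains, x$seed))
  invisible(x)
}

.try_loglik <- function(Kpsi, h2, Y) {
  out <- tryCatch(.loglik_chol(Kpsi, h2, Y), error = function(e) NULL)
  if (!is.null(out) && !is.finite(out$ll)) out <- NULL
  out
}

# log density pieces for the logit random walk on h2 (Jacobian dh/dt = h(1-h))
.h2_log_adjust <- function(h2, prior) {
  stats::dbeta(h2, prior$a, prior$d, log = TRUE) + log(h2) + log1p(-h2)
}

#' Exact conditional draw of the effect vector
#'
#' Draws from the conditional posterior of beta given (h2, psi, Y), which is
#' `N(Sigma X'Y / (1 - h2), Sigma)` with
#' `Sigma = [X'X / (1 - h2) + (h2 diag(psi))^-1]^-1`. No B x B matrix is ever
#' formed: a prior draw `u ~ N(0, h2 psi)` and noise `delta ~ N(0, (1-h2) I)`
#' are corrected through a single n x n solve
#' `(h2 X diag(psi) X' + (1-h2) I) w = Y - (X u + delta)`, returning
#' `u + h2 * psi * (X' w)`. Cost O(n^2 B) per call, independent of B^2.
#'
#' @param data an [model_data()] object.
#' @param h2 fraction of variance explained in (0, 1).
#' @param psi per-feature prior variance shares (default: from
#'   `compute_psi(data$Z, alpha)`, or uniform `1/B` with no annotations).
#' @param alpha annotation weights used to build `psi` when `psi` is `NULL`.
#' @param n_draws number of independent draws (the factorization is reused).
#' @return A numeric vector of length B (one draw) or a B x `n_draws` matrix.
#' @export
sample_beta_conditional <- function(data, h2, psi = NULL, alpha = NULL,
                                    n_draws = 1L) {
  stopifnot(inherits(data, "annovc_data"))
  if (h2 <= 0 || h2 >= 1) stop("'h2' must lie strictly inside (0, 1)")
  if (is.null(psi)) {
    psi <- if (data$M == 0L) {
      rep(1 / data$B, data$B)
    } else {
      compute_psi(data$Z, if (is.null(alpha)) numeric(data$M) else alpha)
    }
  }
  if (length(psi) != data$B) stop("'psi' must have one entry per feature")
  X <- data$X
  Xs <- X * rep(sqrt(psi), each = data$n)
  lc <- .try_loglik(tcrossprod(Xs), h2, data$Y)
  if (is.null(lc)) {
    stop("conditional covariance system is singular (duplicated participants ",
         "or h2 at the boundary)")
  }
  out <- matrix(0, data$B, n_draws)
  for (j in seq_len(n_draws)) {
    out[, j] <- .draw_beta_chol(X, data$Y, h2, psi, lc$chol)
  }
  if (n_draws == 1L) drop(out) else out
}

.draw_beta_chol <- function(X, Y, h2, psi, U) {
  n <- nrow(X)
  B <- ncol(X)
  u <- stats::rnorm(B, 0, sqrt(h2 * psi))
  delta <- stats::rnorm(n, 0, sqrt(1 - h2))
  r <- Y - drop(X %*% u) - delta
  w <- backsolve(U, backsolve(U, r, transpose = TRUE))
  u + h2 * psi * drop(crossprod(X, w))
}

.draw_beta_eigen <- function(X, Y, h2, psi, lam, Q) {
  n <- nrow(X)
  B <- ncol(X)
  u <- stats::rnorm(B, 0, sqrt(h2 * psi))
  delta <- stats::rnorm(n, 0, sqrt(1 - h2))
  r <- Y - drop(X %*% u) - delta
  dvec <- h2 * lam + (1 - h2)
  w <- Q %*% (crossprod(Q, r) / dvec)
  u + h2 * psi * drop(crossprod(X, w))
}

#' One Metropolis update of the annotation weights
#'
#' A single joint Gaussian random-walk proposal on alpha, accepted against the
#' collapsed posterior (marginal likelihood times prior; beta integrated
#' out). Exposed mainly for didactic use and testing; [run_mcmc()] runs the
#' full chain with cached factorizations.
#'
#' @param data an [model_data()] object (with at least one annotation).
#' @param h2 current h2.
#' @param alpha current annotation weights.
#' @param prior an [prior_spec()] object.
#' @param proposal_sd random-walk scale (`0` degenerates to the identity
#'   proposal, which is always accepted).
#' @return List with `alpha`, `accepted`, `log_ratio`.
#' @export
mh_update_alpha <- function(data, h2, alpha, prior = prior_spec(),
                            proposal_sd = 0.3) {
  stopifnot(inherits(data, "annovc_data"), data$M > 0L)
  prop <- alpha + proposal_sd * stats::rnorm(data$M)
  ll0 <- log_marginal_likelihood(data, h2, alpha)
  ll1 <- log_marginal_likelihood(data, h2, prop)
  sa <- sqrt(prior$sigma_alpha_sq)
  logr <- (ll1 - ll0) +
    sum(stats::dnorm(prop, 0, sa, log = TRUE)) -
    sum(stats::dnorm(alpha, 0, sa, log = TRUE))
  acc <- is.finite(logr) && log(stats::runif(1)) < logr
  list(alpha = if (acc) prop else alpha, accepted = acc, log_ratio = logr)
}

#' One Metropolis update of h2
#'
#' A single random-walk proposal on logit(h2) with the Jacobian correction,
#' accepted against the collapsed posterior. Proposals outside
#' `(1e-8, 1 - 1e-8)` are rejected (not clamped) so the stationary
#' distribution is untouched.
#'
#' @inheritParams mh_update_alpha
#' @param proposal_sd random-walk scale on the logit scale.
#' @return List with `h2`, `accepted`, `log_ratio`.
#' @export
mh_update_h2 <- function(data, h2, alpha = numeric(data$M),
                         prior = prior_spec(), proposal_sd = 0.6) {
  stopifnot(inherits(data, "annovc_data"))
  tp <- stats::qlogis(h2) + proposal_sd * stats::rnorm(1)
  h2p <- stats::plogis(tp)
  if (h2p <= 1e-8 || h2p >= 1 - 1e-8) {
    return(list(h2 = h2, accepted = FALSE, log_ratio = -Inf))
  }
  ll0 <- log_marginal_likelihood(data, h2, alpha)
  ll1 <- log_marginal_likelihood(data, h2p, alpha)
  logr <- (ll1 - ll0) + .h2_log_adjust(h2p, prior) - .h2_log_adjust(h2, prior)
  acc <- is.finite(logr) && log(stats::runif(1)) < logr
  list(h2 = if (acc) h2p else h2, accepted = acc, log_ratio = logr)
}

#' Run the collapsed MCMC sampler
#'
#' Posterior sampling for the annotation-informed variance-components model.
#' Each iteration performs (i) a joint Metropolis random-walk update of the
#' annotation weights alpha under the collapsed (beta-marginalized)
#' likelihood, (ii) a Metropolis update of h2 on the logit scale, and, at
#' every recorded iteration, (iii) an exact draw of beta from its conditional
#' posterior together with the realized variance explained
#' `R2 = var(X beta) / var(Y)`. Because beta never feeds back into the
#' collapsed chain, drawing it only at recorded iterations leaves the joint
#' stationary distribution unchanged.
#'
#' Proposal scales are adapted during burn-in only. Chains are independent,
#' with chain `c` seeded at `config$seed + c - 1`.
#'
#' @param data an [model_data()] object.
#' @param prior an [prior_spec()] object.
#' @param config an [mcmc_config()] object.
#' @return An object of class `annovc_draws`: list with `h2` (chains x kept
#'   matrix), `alpha` (chains x kept x M array), `r2` (chains x kept),
#'   `beta` (chains x kept x B array or `NULL`), `beta_mean` (chains x B),
#'   `acceptance` (per-chain acceptance rates after burn-in), `proposal_sd`
#'   (adapted scales), plus the configuration, prior and data dimensions.
#' @seealso [pool_chains()], [summarize_draws()], [trained_coefficients()]
#' @export
run_mcmc <- function(data, prior = prior_spec(), config = mcmc_config()) {
  stopifnot(inherits(data, "annovc_data"), inherits(prior, "annovc_prior"),
            inherits(config, "annovc_mcmc_config"))
  n <- data$n
  B <- data$B
  M <- data$M
  kept <- (config$n_iterations - config$n_burnin) %/% config$thin
  if (kept < 1L) {
    stop("no iterations retained after burn-in and thinning; increase ",
         "'n_iterations' or reduce 'n_burnin'/'thin'")
  }
  store_beta <- config$store_beta
  if (is.null(store_beta)) {
    store_beta <- (as.double(B) * kept * config$n_chains * 8) < 5e8
  }
  pw <- config$likelihood_power

  cache <- .gram_cache(data$X, data$Z)
  use_eigen <- (M == 0L)
  if (use_eigen) {
    K0 <- .kpsi(cache, numeric(0))
    ee <- eigen(K0, symmetric = TRUE)
    lam <- pmax(ee$values, 0)
    Q <- ee$vectors
    ytil2 <- drop(crossprod(Q, data$Y))^2
    psi0 <- rep(1 / B, B)
    loglik_h2 <- function(h2) {
      dvec <- h2 * lam + (1 - h2)
      -0.5 * (n * log(2 * pi) + sum(log(dvec)) + sum(ytil2 / dvec))
    }
  }

  h2_draws <- matrix(NA_real_, config$n_chains, kept)
  alpha_draws <- array(NA_real_, c(config$n_chains, kept, M))
  r2_draws <- matrix(NA_real_, config$n_chains, kept)
  beta_draws <- if (store_beta) array(NA_real_, c(config$n_chains, kept, B)) else NULL
  beta_mean <- matrix(0, config$n_chains, B)
  acc_tab <- data.frame(chain = seq_len(config$n_chains),
                        alpha = NA_real_, h2 = NA_real_)
  sd_tab <- data.frame(chain = seq_len(config$n_chains),
                       alpha = NA_real_, h2 = NA_real_)
  sa_prior <- sqrt(prior$sigma_alpha_sq)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    h2 <- stats::rbeta(1, prior$a, prior$d)
    tries <- 0L
    while ((h2 < 1e-3 || h2 > 1 - 1e-3) && tries < 100L) {
      h2 <- stats::rbeta(1, prior$a, prior$d)
      tries <- tries + 1L
    }
    if (h2 < 1e-3 || h2 > 1 - 1e-3) h2 <- 0.5
    alpha <- numeric(M)

    if (use_eigen) {
      ll <- loglik_h2(h2)
    } else {
      Kpsi <- .kpsi(cache, alpha)
      lc <- .try_loglik(Kpsi, h2, data$Y)
      if (is.null(lc)) {
        stop("non-finite likelihood at initialization; check that the input ",
             "is standardized and free of duplicated participants")
      }
      ll <- lc$ll
      U <- lc$chol
      psi_cur <- .psi_from_cache(cache, alpha)
    }
    if (!is.finite(ll)) {
      stop("non-finite likelihood at initialization; check that the input ",
           "is standardized and free of duplicated participants")
    }

    ls_a <- log(config$proposal_sd_alpha)
    ls_h <- log(config$proposal_sd_h2)
    acc_a <- 0
    acc_h <- 0
    post_iters <- config$n_iterations - config$n_burnin
    k <- 0L

    for (it in seq_len(config$n_iterations)) {
      in_burnin <- it <= config$n_burnin
      gam <- (1 + it)^-0.6

      if (M > 0L) {
        prop <- alpha + exp(ls_a) * stats::rnorm(M)
        Kp <- .kpsi(cache, prop)
        lcp <- .try_loglik(Kp, h2, data$Y)
        if (is.null(lcp)) {
          apr <- 0
        } else {
          logr <- pw * (lcp$ll - ll) +
            sum(stats::dnorm(prop, 0, sa_prior, log = TRUE)) -
            sum(stats::dnorm(alpha, 0, sa_prior, log = TRUE))
          apr <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < apr) {
            alpha <- prop
            Kpsi <- Kp
            ll <- lcp$ll
            U <- lcp$chol
            psi_cur <- .psi_from_cache(cache, alpha)
            acc_a <- acc_a + !in_burnin
          }
        }
        if (config$adapt && in_burnin) ls_a <- ls_a + gam * (apr - 0.25)
      }

      tp <- stats::qlogis(h2) + exp(ls_h) * stats::rnorm(1)
      h2p <- stats::plogis(tp)
      if (h2p <= 1e-8 || h2p >= 1 - 1e-8) {
        apr <- 0
      } else if (use_eigen) {
        llp <- loglik_h2(h2p)
        logr <- pw * (llp - ll) +
          .h2_log_adjust(h2p, prior) - .h2_log_adjust(h2, prior)
        apr <- if (is.finite(logr)) min(1, exp(logr)) else 0
        if (stats::runif(1) < apr) {
          h2 <- h2p
          ll <- llp
          acc_h <- acc_h + !in_burnin
        }
      } else {
        lcp <- .try_loglik(Kpsi, h2p, data$Y)
        if (is.null(lcp)) {
          apr <- 0
        } else {
          logr <- pw * (lcp$ll - ll) +
            .h2_log_adjust(h2p, prior) - .h2_log_adjust(h2, prior)
          apr <- if (is.finite(logr)) min(1, exp(logr)) else 0
          if (stats::runif(1) < apr) {
            h2 <- h2p
            ll <- lcp$ll
            U <- lcp$chol
            acc_h <- acc_h + !in_burnin
          }
        }
      }
      if (config$adapt && in_burnin) ls_h <- ls_h + gam * (apr - 0.40)

      if (!in_burnin && (it - config$n_burnin) %% config$thin == 0L) {
        k <- k + 1L
        beta <- if (use_eigen) {
          .draw_beta_eigen(data$X, data$Y, h2, psi0, lam, Q)
        } else {
          .draw_beta_chol(data$X, data$Y, h2, psi_cur, U)
        }
        h2_draws[ch, k] <- h2
        if (M > 0L) alpha_draws[ch, k, ] <- alpha
        r2_draws[ch, k] <- stats::var(drop(data$X %*% beta)) / stats::var(data$Y)
        if (store_beta) beta_draws[ch, k, ] <- beta
        beta_mean[ch, ] <- beta_mean[ch, ] + beta
      }
    }
    beta_mean[ch, ] <- beta_mean[ch, ] / kept
    acc_tab$alpha[ch] <- if (M > 0L) acc_a / post_iters else NA_real_
    acc_tab$h2[ch] <- acc_h / post_iters
    sd_tab$alpha[ch] <- if (M > 0L) exp(ls_a) else NA_real_
    sd_tab$h2[ch] <- exp(ls_h)
  }

  structure(
    list(h2 = h2_draws, alpha = alpha_draws, r2 = r2_draws,
         beta = beta_draws, beta_mean = beta_mean,
         acceptance = acc_tab, proposal_sd = sd_tab, kept = kept,
         config = config, prior = prior,
         n = n, B = B, M = M,
         feature_ids = data$feature_ids,
         annotation_names = data$annotation_names),
    class = "annovc_draws"
  )
}

#' @export
print.annovc_draws <- function(x, ...) {
  cat(sprintf(
    "annovc_draws: %d chain(s) x %d kept draws (n = %d, B = %d, M = %d)\n",
    nrow(x$h2), x$kept, x$n, x$B, x$M))
  cat(sprintf("  pooled median h2 = %.3f\n", stats::median(x$h2)))
  invisible(x)
}
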