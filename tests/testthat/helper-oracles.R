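# Independent oracles and small-data builders shared across tests.

std_cols <- function(X) {
  X <- sweep(X, 2L, colMeans(X))
  sweep(X, 2L, sqrt(colSums(X^2) / (nrow(X) - 1)), "/")
}

std_vec <- function(y) (y - mean(y)) / stats::sd(y)

# Marginal log likelihood through the B-dimensional (Woodbury) route:
# V = (1-h2) (I_n + c X Psi X') with c = h2/(1-h2), so
# log|V| = n log(1-h2) + log|A|,  A = I_B + c Psi^{1/2} X'X Psi^{1/2},
# V^{-1} y = (y - c X Psi^{1/2} A^{-1} Psi^{1/2} X' y) / (1-h2).
# Algebraically independent of the package's n x n Cholesky path.
oracle_log_marginal <- function(X, Y, h2, psi) {
  n <- nrow(X)
  B <- ncol(X)
  cc <- h2 / (1 - h2)
  Xs <- X * rep(sqrt(psi), each = n)
  A <- diag(B) + cc * crossprod(Xs)
  xty <- drop(crossprod(Xs, Y))
  quad <- (sum(Y^2) - cc * sum(xty * solve(A, xty))) / (1 - h2)
  ld <- n * log(1 - h2) + determinant(A, logarithm = TRUE)$modulus
  -0.5 * (n * log(2 * pi) + as.numeric(ld) + quad)
}

# Dense-formula conditional posterior of beta (feasible only for small B).
oracle_beta_posterior <- function(X, Y, h2, psi) {
  Sigma <- solve(crossprod(X) / (1 - h2) + diag(1 / (h2 * psi)))
  list(mean = drop(Sigma %*% crossprod(X, Y)) / (1 - h2), cov = Sigma)
}

# Uncollapsed MH-within-Gibbs sampler: beta drawn exactly from its dense
# conditional, then random-walk Metropolis on h2 and alpha GIVEN beta.
# Targets the same joint posterior as the collapsed chain; used only as a
# cross-check on tiny instances.
uncollapsed_mcmc <- function(data, prior, n_iterations, n_burnin, thin,
                             sd_h2 = 0.4, sd_alpha = 0.4) {
  n <- data$n; B <- data$B; M <- data$M
  X <- data$X; Y <- data$Y
  h2 <- 0.5
  alpha <- numeric(M)
  psi <- if (M > 0) compute_psi(data$Z, alpha) else rep(1 / B, B)
  kept <- (n_iterations - n_burnin) %/% thin
  out_h2 <- numeric(kept)
  out_alpha <- matrix(NA_real_, kept, M)
  k <- 0L
  log_cond <- function(h2, psi, beta) {
    sum(stats::dnorm(beta, 0, sqrt(h2 * psi), log = TRUE)) +
      sum(stats::dnorm(Y - drop(X %*% beta), 0, sqrt(1 - h2), log = TRUE)) +
      stats::dbeta(h2, prior$a, prior$d, log = TRUE)
  }
  for (it in seq_len(n_iterations)) {
    post <- oracle_beta_posterior(X, Y, h2, psi)
    beta <- drop(post$mean +
                   t(chol(post$cov)) %*% stats::rnorm(B))
    # h2 on logit scale
    tp <- stats::qlogis(h2) + sd_h2 * stats::rnorm(1)
    h2p <- stats::plogis(tp)
    if (h2p > 1e-8 && h2p < 1 - 1e-8) {
      logr <- log_cond(h2p, psi, beta) - log_cond(h2, psi, beta) +
        log(h2p) + log1p(-h2p) - log(h2) - log1p(-h2)
      if (log(stats::runif(1)) < logr) h2 <- h2p
    }
    if (M > 0) {
      prop <- alpha + sd_alpha * stats::rnorm(M)
      psip <- compute_psi(data$Z, prop)
      sa <- sqrt(prior$sigma_alpha_sq)
      logr <- sum(stats::dnorm(beta, 0, sqrt(h2 * psip), log = TRUE)) -
        sum(stats::dnorm(beta, 0, sqrt(h2 * psi), log = TRUE)) +
        sum(stats::dnorm(prop, 0, sa, log = TRUE)) -
        sum(stats::dnorm(alpha, 0, sa, log = TRUE))
      if (log(stats::runif(1)) < logr) {
        alpha <- prop
        psi <- psip
      }
    }
    if (it > n_burnin && (it - n_burnin) %% thin == 0L) {
      k <- k + 1L
      out_h2[k] <- h2
      if (M > 0) out_alpha[k, ] <- alpha
    }
  }
  list(h2 = out_h2, alpha = out_alpha)
}

# batch-means Monte Carlo standard error
batch_se <- function(x, n_batches = 20L) {
  L <- length(x) %/% n_batches * n_batches
  bm <- colMeans(matrix(x[seq_len(L)], ncol = n_batches))
  stats::sd(bm) / sqrt(n_batches)
}

# a small standardized dataset with optional binary annotations
tiny_dataset <- function(n, B, M = 0L, h2 = 0.5, alpha = numeric(M),
                         fractions = rep(0.25, M), seed = 1) {
  set.seed(seed)
  X <- std_cols(matrix(stats::rnorm(n * B), n, B))
  Z <- if (M > 0) simulate_annotations(B, M, fractions) else NULL
  psi <- if (M > 0) compute_psi(Z, alpha) else rep(1 / B, B)
  beta <- stats::rnorm(B, 0, sqrt(h2 * psi))
  Y <- std_vec(drop(X %*% beta) + stats::rnorm(n, sd = sqrt(1 - h2)))
  model_data(X, Y, Z, check_standardized = FALSE)
}
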