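test_that("conditional beta draw matches the dense-formula posterior", {
  set.seed(21)
  n <- 120; B <- 12
  X <- std_cols(matrix(rnorm(n * B), n, B))
  beta0 <- rnorm(B, sd = sqrt(0.5 / B))
  Y <- std_vec(drop(X %*% beta0) + rnorm(n, sd = sqrt(0.5)))
  d <- model_data(X, Y, check_standardized = FALSE)
  h2 <- 0.5
  psi <- rep(1 / B, B)
  post <- oracle_beta_posterior(X, Y, h2, psi)

  N <- 4000
  draws <- sample_beta_conditional(d, h2, psi = psi, n_draws = N)
  m <- rowMeans(draws)
  # Mahalanobis distance of the empirical mean under cov/N
  md <- drop(t(m - post$mean) %*% solve(post$cov / N, m - post$mean))
  expect_lt(md, qchisq(0.9999, df = B))
  emp_cov <- stats::cov(t(draws))
  expect_lt(norm(emp_cov - post$cov, "F") / norm(post$cov, "F"), 0.15)
})

test_that("conditional beta draw is centred at zero when Y = 0 and collapses with psi", {
  set.seed(22)
  n <- 80; B <- 6
  X <- std_cols(matrix(rnorm(n * B), n, B))
  d <- model_data(X, rep(0, n), check_standardized = FALSE)
  draws <- sample_beta_conditional(d, 0.4, psi = rep(1 / B, B), n_draws = 2000)
  post <- oracle_beta_posterior(X, rep(0, n), 0.4, rep(1 / B, B))
  se <- sqrt(diag(post$cov) / 2000)
  expect_true(all(abs(rowMeans(draws)) < 5 * se))

  # a vanishing prior variance share pins that coefficient at zero
  psi <- c(1e-12, rep((1 - 1e-12) / (B - 1), B - 1))
  d2 <- model_data(X, std_vec(rnorm(n)), check_standardized = FALSE)
  dr <- sample_beta_conditional(d2, 0.4, psi = psi, n_draws = 200)
  expect_lt(max(abs(dr[1, ])), 1e-4)
})

test_that("single Metropolis steps behave at degenerate proposal scales", {
  set.seed(23)
  d <- tiny_dataset(40, 20, M = 1, alpha = 0.3, fractions = 0.3)
  up <- mh_update_alpha(d, 0.5, 0.1, proposal_sd = 0)
  expect_true(up$accepted)
  expect_equal(up$alpha, 0.1)
  up2 <- mh_update_h2(d, 0.5, 0.1, proposal_sd = 1e-12)
  expect_true(up2$accepted)
})

test_that("a near-degenerate alpha prior pins the weights and recovers the homoscedastic fit", {
  set.seed(24)
  d <- tiny_dataset(150, 300, M = 1, h2 = 0.5, alpha = 0, fractions = 0.3,
                    seed = 31)
  cfg <- mcmc_config(800, 300, 2, n_chains = 1, seed = 5)
  dr_pinned <- run_mcmc(d, prior_spec(sigma_alpha_sq = 1e-10), cfg)
  expect_lt(max(abs(dr_pinned$alpha)), 1e-3)

  d0 <- model_data(d$X, d$Y, check_standardized = FALSE)
  dr0 <- run_mcmc(d0, prior_spec(), cfg)
  expect_lt(abs(median(dr_pinned$h2) - median(dr0$h2)), 0.1)
})

test_that("pure-noise data concentrate h2 near zero", {
  set.seed(25)
  n <- 500; B <- 1000
  X <- std_cols(matrix(rnorm(n * B), n, B))
  Y <- std_vec(rnorm(n))
  d <- model_data(X, Y, check_standardized = FALSE)
  dr <- run_mcmc(d, prior_spec(), mcmc_config(1500, 500, 2, n_chains = 2, seed = 9))
  expect_lt(median(dr$h2), 0.1)
})

test_that("collapsed and uncollapsed samplers agree on a small instance", {
  set.seed(26)
  d <- tiny_dataset(60, 10, M = 1, h2 = 0.5, alpha = 0.5, fractions = 0.4,
                    seed = 41)
  pr <- prior_spec(sigma_alpha_sq = 0.5)
  dr <- run_mcmc(d, pr, mcmc_config(6000, 1000, 2, n_chains = 2, seed = 11))
  h2_c <- pool_chains(dr)$h2
  a_c <- pool_chains(dr)$alpha[, 1]

  set.seed(27)
  unc <- uncollapsed_mcmc(d, pr, n_iterations = 12000, n_burnin = 2000,
                          thin = 4)
  se <- sqrt(batch_se(h2_c)^2 + batch_se(unc$h2)^2)
  expect_lt(abs(mean(h2_c) - mean(unc$h2)), 3 * se + 1e-8)
  se_a <- sqrt(batch_se(a_c)^2 + batch_se(unc$alpha[, 1])^2)
  expect_lt(abs(mean(a_c) - mean(unc$alpha[, 1])), 3 * se_a + 1e-8)
})

test_that("adapted acceptance rates land in a healthy band", {
  set.seed(28)
  sim <- simulate_dataset(simulation_config(
    n = 200, B = 400, M = 3, h2_true = 0.5, alpha_true = c(-1, 0.5, 0),
    annotation_fractions = rep(0.1, 3), seed = 51))
  dr <- run_mcmc(sim$data, prior_spec(), mcmc_config(800, 300, 2,
                                                     n_chains = 2, seed = 3))
  expect_true(all(dr$acceptance$alpha > 0.1 & dr$acceptance$alpha < 0.6))
  expect_true(all(dr$acceptance$h2 > 0.1 & dr$acceptance$h2 < 0.6))
})

test_that("chains are reproducible from the seed and schedules validate", {
  d <- tiny_dataset(50, 30, seed = 61)
  cfg <- mcmc_config(200, 50, 2, n_chains = 2, seed = 7)
  dr1 <- run_mcmc(d, prior_spec(), cfg)
  dr2 <- run_mcmc(d, prior_spec(), cfg)
  expect_identical(dr1$h2, dr2$h2)
  expect_identical(dr1$beta_mean, dr2$beta_mean)
  dr3 <- run_mcmc(d, prior_spec(), mcmc_config(200, 50, 2, n_chains = 2,
                                               seed = 8))
  expect_false(identical(dr1$h2, dr3$h2))

  expect_error(mcmc_config(100, 100, 1), "n_burnin")
  expect_error(mcmc_config(100, 0, 0), "thin")
  expect_error(run_mcmc(d, prior_spec(),
                        mcmc_config(100, 99, 10, n_chains = 1)),
               "retained")
})

test_that("h2 draws stay inside the open unit interval and R2 is nonnegative", {
  d <- tiny_dataset(60, 40, seed = 71)
  dr <- run_mcmc(d, prior_spec(), mcmc_config(400, 100, 3, n_chains = 1,
                                              seed = 13))
  expect_true(all(dr$h2 > 0 & dr$h2 < 1))
  expect_true(all(dr$r2 >= 0))
  expect_equal(dr$kept, 100L)
})
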