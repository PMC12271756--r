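test_that("softmax variance shares reduce to 1/B at alpha = 0 and match hand evaluation", {
  Z <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(compute_psi(Z, c(0, 0, 0)), rep(0.25, 4))

  # single binary column, features 1 and 2 annotated, weight log 2:
  # scores (log2, log2, 0, 0) -> (2,2,1,1)/6
  Z1 <- matrix(c(1, 1, 0, 0), ncol = 1)
  expect_equal(compute_psi(Z1, log(2)), c(1/3, 1/3, 1/6, 1/6))
})

test_that("annotated-to-unannotated weight ratio equals the enrichment ratio", {
  Z1 <- matrix(c(1, 0, 0, 0, 1, 0), ncol = 1)
  psi <- compute_psi(Z1, 0.19)
  expect_equal(round(psi[1] / psi[2], 2), 1.21)
  expect_equal(psi[1] / psi[2], enrichment_ratio(0.19))
})

test_that("variance shares sum to one, survive extreme scores, and are shift invariant", {
  set.seed(7)
  for (B in c(11, 500, 1e5)) {
    Z <- matrix(rnorm(B * 2), B, 2)
    psi <- compute_psi(Z, c(1.3, -0.7))
    expect_true(all(psi > 0))
    expect_equal(sum(psi), 1, tolerance = 1e-10)
  }
  # scores at +/-700 would overflow exp() evaluated naively
  Zbig <- matrix(c(700, -700, 350, 0), ncol = 1)
  psi <- compute_psi(Zbig, 1)
  expect_true(all(is.finite(psi)))
  expect_equal(sum(psi), 1, tolerance = 1e-10)

  # adding a constant score to every feature leaves the shares unchanged
  Z <- matrix(rbinom(40, 1, 0.3), ncol = 2)
  expect_equal(compute_psi(cbind(Z, 1), c(0.4, -1.1, 57)),
               compute_psi(Z, c(0.4, -1.1)), tolerance = 1e-12)
})

test_that("variance-share computation rejects malformed input", {
  Z <- matrix(0, 5, 2)
  expect_error(compute_psi(Z, 1), "ncol")
  expect_error(compute_psi(Z, c(1, NaN)), "finite")
})

test_that("enrichment ratio is exp(alpha)", {
  expect_equal(round(enrichment_ratio(0.19), 2), 1.21)
  expect_identical(enrichment_ratio(0), 1)
  expect_equal(round(enrichment_ratio(-1.13), 3), 0.323)
  expect_error(enrichment_ratio(Inf), "finite")
})

test_that("log prior matches closed forms and enforces the open h2 interval", {
  pr <- prior_spec(a = 1, d = 1, sigma_alpha_sq = 1)
  # flat Beta contributes 0; standard normal at 0 contributes -log(2*pi)/2
  expect_equal(log_prior(0.3, 0, pr), -0.5 * log(2 * pi))

  expect_error(log_prior(0, numeric(0), pr), "inside")
  expect_error(log_prior(1, numeric(0), pr), "inside")

  # beta term: independent normals with variance h2 * psi
  psi <- c(0.5, 0.5)
  lp <- log_prior(0.5, numeric(0), pr, psi = psi, beta = c(0, 0))
  byhand <- stats::dbeta(0.5, 1, 1, log = TRUE) +
    sum(-0.5 * log(2 * pi * 0.5 * psi))
  expect_equal(lp, byhand)
})

test_that("marginal likelihood matches the unit-variance normal in the 1x1 case", {
  d <- model_data(matrix(1, 1, 1), 0, check_standardized = FALSE)
  expect_equal(log_marginal_likelihood(d, 0.5), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(round(log_marginal_likelihood(d, 0.5), 3), -0.919)
})

test_that("marginal likelihood agrees with the B-side Woodbury oracle", {
  set.seed(11)
  # dense annotation path (continuous Z: every feature its own profile)
  for (rep in 1:3) {
    n <- sample(3:50, 1)
    B <- sample(2:8, 1)
    X <- matrix(rnorm(n * B), n, B)
    Z <- matrix(rnorm(B * 2), B, 2)
    Y <- rnorm(n)
    alpha <- rnorm(2, sd = 0.8)
    h2 <- runif(1, 0.1, 0.9)
    d <- model_data(X, Y, Z, check_standardized = FALSE)
    expect_equal(log_marginal_likelihood(d, h2, alpha),
                 oracle_log_marginal(X, Y, h2, compute_psi(Z, alpha)),
                 tolerance = 1e-8)
  }
  # grouped path (binary annotations, B > n)
  n <- 20; B <- 40
  X <- matrix(rnorm(n * B), n, B)
  Z <- simulate_annotations(B, 3, c(0.2, 0.2, 0.2))
  Y <- rnorm(n)
  alpha <- c(-1, 0.5, 0.2)
  d <- model_data(X, Y, Z, check_standardized = FALSE)
  expect_equal(log_marginal_likelihood(d, 0.45, alpha),
               oracle_log_marginal(X, Y, 0.45, compute_psi(Z, alpha)),
               tolerance = 1e-8)
})

test_that("marginal likelihood is invariant to permuting features with their annotations", {
  set.seed(3)
  n <- 15; B <- 30
  X <- matrix(rnorm(n * B), n, B)
  Z <- simulate_annotations(B, 2, c(0.3, 0.2))
  Y <- rnorm(n)
  d1 <- model_data(X, Y, Z, check_standardized = FALSE)
  perm <- sample(B)
  d2 <- model_data(X[, perm], Y, Z[perm, ], check_standardized = FALSE)
  a <- c(0.7, -0.4)
  expect_equal(log_marginal_likelihood(d1, 0.6, a),
               log_marginal_likelihood(d2, 0.6, a), tolerance = 1e-10)
})

test_that("marginal likelihood is finite up to both h2 boundaries", {
  set.seed(5)
  d <- tiny_dataset(30, 60)
  grid <- c(1e-6, 1e-4, 0.01, seq(0.1, 0.9, by = 0.2), 0.99, 1 - 1e-4, 1 - 1e-6)
  ll <- vapply(grid, function(h) log_marginal_likelihood(d, h), numeric(1))
  expect_true(all(is.finite(ll)))
  expect_error(log_marginal_likelihood(d, 0), "inside")
  expect_error(log_marginal_likelihood(d, 1.2), "inside")
})

test_that("alpha = 0 implies the homoscedastic effect-prior covariance h2/B", {
  Z <- matrix(rbinom(200 * 4, 1, 0.2), 200, 4)
  psi <- compute_psi(Z, rep(0, 4))
  h2 <- 0.37
  expect_equal(h2 * psi, rep(h2 / 200, 200))
})

test_that("prior spec validates hyperparameters", {
  expect_error(prior_spec(a = 0), "positive")
  expect_error(prior_spec(d = -1), "positive")
  expect_error(prior_spec(sigma_alpha_sq = 0), "positive")
})
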