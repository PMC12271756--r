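#' Simulation configuration
#'
#' Describes one synthetic study: dimensions, the generating parameter
#' values, the serial-correlation parameter of the effect vector, and the
#' design-matrix correlation model.
#'
#' The defaults reproduce the package's desk-scale Monte Carlo conditions:
#' n = 600 participants and B = 3000 features (a 1:5 participant:feature
#' ratio), M = 10 disjoint binary annotations each covering 8% of features
#' (annotated features contiguous, so serial correlation of effects runs
#' along annotation blocks, mimicking network-adjacent edges), and annotation
#' weights with two nonzero entries, `alpha_true[1] = -1.13` and
#' `alpha_true[2] = 0.38`.
#'
#' @param n participants.
#' @param B features.
#' @param M number of binary annotations (0 for the homoscedastic model).
#' @param h2_true generating fraction of variance explained, in (0, 1).
#' @param alpha_true length-M generating annotation weights.
#' @param rho AR(1) correlation of the effect vector along the feature
#'   ordering, in `[0, 1)`; `rho = 0` matches the model's independent prior.
#' @param x_model design-matrix correlation model: `"iid"`, `"equicorrelated"`
#'   or `"block"` (blocks of `block_size` columns sharing correlation
#'   `x_cor`).
#' @param x_cor within-block (or common) column correlation for the
#'   correlated design models.
#' @param block_size block width for `x_model = "block"`.
#' @param annotation_fractions per-annotation fraction of features annotated.
#' @param disjoint_annotations make annotation columns disjoint (required
#'   when the fractions sum to more than 1 this errors).
#' @param standardize_y standardize the simulated phenotype (default TRUE;
#'   the scaling is recorded on the dataset).
#' @param seed optional seed applied by [simulate_dataset()].
#' @return An object of class `annovc_sim_config`.
#' @export
simulation_config <- function(n = 600L, B = 3000L, M = 10L,
                              h2_true = 0.4,
                              alpha_true = c(-1.13, 0.38,
                                             rep(0, max(0, M - 2L)))[seq_len(M)],
                              rho = 0,
                              x_model = c("iid", "equicorrelated", "block"),
                              x_cor = 0.5, block_size = 10L,
                              annotation_fractions = rep(0.08, M),
                              disjoint_annotations = TRUE,
                              standardize_y = TRUE, seed = NULL) {
  x_model <- match.arg(x_model)
  n <- as.integer(n); B <- as.integer(B); M <- as.integer(M)
  if (n < 2L || B < 2L) stop("'n' and 'B' must both be at least 2")
  if (h2_true <= 0 || h2_true >= 1) stop("'h2_true' must lie in (0, 1)")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  if (M > 0L) {
    if (length(alpha_true) != M) stop("'alpha_true' must have length M")
    if (length(annotation_fractions) != M) {
      stop("'annotation_fractions' must have length M")
    }
    if (any(annotation_fractions < 0) || any(annotation_fractions > 1)) {
      stop("'annotation_fractions' must lie in [0, 1]")
    }
  }
  structure(
    list(n = n, B = B, M = M, h2_true = h2_true,
         alpha_true = if (M > 0L) alpha_true else numeric(0),
         rho = rho, x_model = x_model, x_cor = x_cor,
         block_size = as.integer(block_size),
         annotation_fractions = if (M > 0L) annotation_fractions else numeric(0),
         disjoint_annotations = isTRUE(disjoint_annotations),
         standardize_y = isTRUE(standardize_y), seed = seed),
    class = "annovc_sim_config"
  )
}

#' Simulate a standardized design matrix
#'
#' Generates an n x B Gaussian design with one of three column-correlation
#' structures and standardizes every column to mean 0 and unit (n-1
#' denominator) variance afterwards.
#'
#' @param n,B dimensions.
#' @param x_model `"iid"`, `"equicorrelated"` or `"block"`.
#' @param x_cor target column correlation for the correlated models.
#' @param block_size number of consecutive columns per correlated block.
#' @return An n x B matrix with standardized columns.
#' @export
simulate_design <- function(n, B, x_model = c("iid", "equicorrelated", "block"),
                            x_cor = 0.5, block_size = 10L) {
  x_model <- match.arg(x_model)
  if (n < 2L || B < 2L) stop("'n' and 'B' must both be at least 2")
  X <- matrix(stats::rnorm(n * B), n, B)
  if (x_model == "equicorrelated") {
    common <- stats::rnorm(n)
    X <- sqrt(x_cor) * common + sqrt(1 - x_cor) * X
  } else if (x_model == "block") {
    block_size <- as.integer(block_size)
    if (block_size < 2L || block_size > B) {
      stop("'block_size' must lie in [2, B]")
    }
    blk <- rep(seq_len(ceiling(B / block_size)), each = block_size)[seq_len(B)]
    common <- matrix(stats::rnorm(n * max(blk)), n, max(blk))
    X <- sqrt(x_cor) * common[, blk] + sqrt(1 - x_cor) * X
  }
  .standardize_cols(X)
}

.standardize_cols <- function(X) {
  cm <- colMeans(X)
  X <- sweep(X, 2L, cm)
  csd <- sqrt(colSums(X^2) / (nrow(X) - 1))
  if (any(csd == 0)) stop("constant column produced during simulation")
  sweep(X, 2L, csd, "/")
}

#' Simulate binary feature annotations
#'
#' Builds a features x annotations binary matrix in which column m annotates
#' `round(B * fractions[m])` features. With `disjoint = TRUE` (default)
#' annotated features are contiguous, non-overlapping blocks starting at
#' feature 1 — the ordering convention under which AR(1) effect correlation
#' runs along annotation blocks.
#'
#' @param B number of features.
#' @param M number of annotations.
#' @param fractions per-annotation fraction of features annotated; each must
#'   give at least one feature, and with `disjoint = TRUE` they must sum to
#'   at most 1.
#' @param disjoint forbid overlap between annotation columns; when `FALSE`
#'   each column independently samples its features at random.
#' @return A B x M binary matrix with columns named `"A1" ... "AM"`.
#' @export
simulate_annotations <- function(B, M, fractions = rep(0.08, M),
                                 disjoint = TRUE) {
  B <- as.integer(B); M <- as.integer(M)
  if (length(fractions) != M) stop("'fractions' must have length M")
  counts <- round(B * fractions)
  if (any(counts < 1)) {
    stop("annotation fraction(s) ", paste(which(counts < 1), collapse = ", "),
         " annotate no features at B = ", B)
  }
  Z <- matrix(0, B, M, dimnames = list(NULL, paste0("A", seq_len(M))))
  if (disjoint) {
    if (sum(counts) > B) {
      stop("disjoint annotations require fractions summing to at most 1")
    }
    at <- 0L
    for (m in seq_len(M)) {
      Z[(at + 1L):(at + counts[m]), m] <- 1
      at <- at + counts[m]
    }
  } else {
    for (m in seq_len(M)) {
      Z[sample.int(B, counts[m]), m] <- 1
    }
  }
  Z
}

#' Simulate an AR(1)-correlated effect vector
#'
#' Draws beta with the prior marginal variances `h2 * psi_k` but serial
#' correlation `Corr(beta_k, beta_k') = rho^|k - k'|` along the feature
#' index: a stationary standard AR(1) sequence `u` is scaled by
#' `sqrt(h2 * psi_k)`. At `rho = 0` this is exactly the model's independent
#' heteroscedastic prior; `rho > 0` violates the prior's independence
#' assumption while preserving every marginal variance, so the covariance is
#' `h2 * sqrt(psi_k psi_k') * rho^|k-k'|`.
#'
#' @param h2_true total prior effect variance, in (0, 1).
#' @param psi per-feature variance shares (summing to one), e.g. from
#'   [compute_psi()].
#' @param rho AR(1) parameter in `[0, 1)`.
#' @return A numeric effect vector of length `length(psi)`.
#' @export
simulate_beta_ar1 <- function(h2_true, psi, rho = 0) {
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  B <- length(psi)
  if (rho == 0) {
    u <- stats::rnorm(B)
  } else {
    u <- numeric(B)
    u[1] <- stats::rnorm(1)
    innov <- stats::rnorm(B - 1L, sd = sqrt(1 - rho^2))
    for (k in 2:B) u[k] <- rho * u[k - 1L] + innov[k - 1L]
  }
  sqrt(h2_true * psi) * u
}

#' Simulate the phenotype
#'
#' `Y = X beta + eps` with `eps ~ N(0, (1 - h2) I)`. When `standardize`
#' is `TRUE` the returned phenotype is centred and scaled to unit variance
#' and the applied scale is attached as attribute `"scale"`.
#'
#' @param X design matrix (standardized columns).
#' @param beta_true effect vector of length `ncol(X)`.
#' @param h2_true generating h2 (noise variance is `1 - h2_true`).
#' @param standardize standardize the phenotype after generation.
#' @return Numeric phenotype vector of length `nrow(X)`.
#' @export
simulate_outcome <- function(X, beta_true, h2_true, standardize = TRUE) {
  if (length(beta_true) != ncol(X)) stop("'beta_true' must match ncol(X)")
  Y <- drop(X %*% beta_true) + stats::rnorm(nrow(X), sd = sqrt(1 - h2_true))
  if (standardize) {
    s <- stats::sd(Y)
    Y <- (Y - mean(Y)) / s
    attr(Y, "scale") <- s
  }
  Y
}

#' Simulate a complete data set
#'
#' Puts [simulate_design()], [simulate_annotations()], [compute_psi()],
#' [simulate_beta_ar1()] and [simulate_outcome()] together under one
#' configuration.
#'
#' @param config an [simulation_config()] object.
#' @return An object of class `annovc_sim`: list with `data` (an
#'   [model_data()] object), `beta_true`, `psi_true` and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "annovc_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  X <- simulate_design(config$n, config$B, config$x_model, config$x_cor,
                       config$block_size)
  Z <- NULL
  psi <- rep(1 / config$B, config$B)
  if (config$M > 0L) {
    Z <- simulate_annotations(config$B, config$M, config$annotation_fractions,
                              disjoint = config$disjoint_annotations)
    psi <- compute_psi(Z, config$alpha_true)
  }
  beta <- simulate_beta_ar1(config$h2_true, psi, config$rho)
  Y <- simulate_outcome(X, beta, config$h2_true,
                        standardize = config$standardize_y)
  data <- model_data(X, as.numeric(Y), Z, check_standardized = FALSE)
  structure(list(data = data, beta_true = beta, psi_true = psi,
                 config = config),
            class = "annovc_sim")
}

#' @export
print.annovc_sim <- function(x, ...) {
  cat(sprintf(
    "annovc_sim: n = %d, B = %d, M = %d, h2_true = %g, rho = %g (%s design)\n",
    x$config$n, x$config$B, x$config$M, x$config$h2_true, x$config$rho,
    x$config$x_model))
  invisible(x)
}

#' Monte Carlo parameter-recovery grid experiment
#'
#' For every combination of `rho_grid` and `h2_grid`, simulates a data set
#' under the AR(1)-correlated effect prior, fits the model with
#' `chains_per_setting` independent chains, and scores recovery: pooled
#' posterior summaries of h2 and the first two annotation weights, per-chain
#' 95% credible-interval containment of the generating values, the pooled
#' per-feature coverage of beta, and the pooled median realized R2.
#'
#' The design matrix and annotation matrix are generated once and reused
#' across settings, mirroring a fixed imaging design.
#'
#' @param rho_grid,h2_grid grids of generating values.
#' @param config an [simulation_config()] giving dimensions, annotation
#'   layout and design model (its `h2_true`/`rho` entries are overridden by
#'   the grid).
#' @param prior an [prior_spec()].
#' @param chains_per_setting independent chains per setting.
#' @param n_iterations,n_burnin,thin chain schedule.
#' @param seed base seed; setting s uses `seed + 100 * s` for data and chains.
#' @return An object of class `annovc_grid`: a data frame with one row per
#'   setting (posterior means/medians, CI bounds, per-chain containment
#'   counts `cover_*` out of `chains_per_setting`, `beta_coverage`,
#'   `r2_median`), with the per-setting draws' pooled summaries in
#'   `attr(, "details")`.
#' @export
run_grid_experiment <- function(rho_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                                h2_grid = c(0.2, 0.4, 0.6, 0.8),
                                config = simulation_config(),
                                prior = prior_spec(),
                                chains_per_setting = 10L,
                                n_iterations = 2000L, n_burnin = 800L,
                                thin = 4L, seed = 1L) {
  settings <- expand.grid(rho = rho_grid, h2_true = h2_grid,
                          KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  X <- simulate_design(config$n, config$B, config$x_model, config$x_cor,
                       config$block_size)
  Z <- if (config$M > 0L) {
    simulate_annotations(config$B, config$M, config$annotation_fractions,
                         disjoint = config$disjoint_annotations)
  } else NULL
  psi <- if (is.null(Z)) rep(1 / config$B, config$B) else {
    compute_psi(Z, config$alpha_true)
  }

  rows <- vector("list", nrow(settings))
  details <- vector("list", nrow(settings))
  for (s in seq_len(nrow(settings))) {
    rho <- settings$rho[s]
    h2t <- settings$h2_true[s]
    set.seed(seed + 100L * s)
    beta <- simulate_beta_ar1(h2t, psi, rho)
    Y <- simulate_outcome(X, beta, h2t, standardize = config$standardize_y)
    dat <- model_data(X, as.numeric(Y), Z, check_standardized = FALSE)
    draws <- run_mcmc(dat, prior, mcmc_config(
      n_iterations = n_iterations, n_burnin = n_burnin, thin = thin,
      n_chains = chains_per_setting, seed = seed + 100L * s + 1L,
      store_beta = TRUE))
    truth <- list(h2 = h2t, alpha = config$alpha_true, beta = beta)
    cov <- evaluate_coverage(draws, truth)
    pooled <- pool_chains(draws)
    row <- data.frame(
      rho = rho, h2_true = h2t,
      h2_mean = mean(pooled$h2), h2_median = stats::median(pooled$h2),
      h2_lower = stats::quantile(pooled$h2, 0.025, names = FALSE),
      h2_upper = stats::quantile(pooled$h2, 0.975, names = FALSE),
      r2_median = stats::median(pooled$r2),
      beta_coverage = cov$beta_coverage,
      cover_h2 = cov$chain_containment["h2"]
    )
    if (config$M >= 2L) {
      row$alpha1_mean <- mean(pooled$alpha[, 1])
      row$alpha1_lower <- stats::quantile(pooled$alpha[, 1], 0.025, names = FALSE)
      row$alpha1_upper <- stats::quantile(pooled$alpha[, 1], 0.975, names = FALSE)
      row$alpha2_mean <- mean(pooled$alpha[, 2])
      row$alpha2_lower <- stats::quantile(pooled$alpha[, 2], 0.025, names = FALSE)
      row$alpha2_upper <- stats::quantile(pooled$alpha[, 2], 0.975, names = FALSE)
      row$cover_alpha1 <- cov$chain_containment["alpha1"]
      row$cover_alpha2 <- cov$chain_containment["alpha2"]
    }
    rows[[s]] <- row
    details[[s]] <- list(coverage = cov, acceptance = draws$acceptance)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  attr(out, "chains_per_setting") <- chains_per_setting
  class(out) <- c("annovc_grid", "data.frame")
  out
}

#' Train/test shrinkage experiment
#'
#' Replicates the out-of-sample drop-off experiment under the homoscedastic
#' (no-annotation) prior: a design of `n_train + n_test` participants is
#' split at random `n_splits` times; for each split the effect vector is
#' drawn from the `N(0, h2_true / B)` prior, phenotypes are generated on the
#' separately standardized train and test designs, the model is fitted on
#' the training half, and the squared correlation between
#' `X_test %*% beta_hat` and `Y_test` gives the out-of-sample h2 estimate.
#'
#' @param h2_true generating fraction of variance explained.
#' @param n_train,n_test split sizes.
#' @param B number of features.
#' @param n_splits number of random splits.
#' @param prior an [prior_spec()].
#' @param n_chains,n_iterations,n_burnin,thin chain schedule per split.
#' @param seed base seed.
#' @return An object of class `annovc_shrinkage`: data frame with one row
#'   per split (`h2_in`, posterior-median in-sample h2; `h2_out`,
#'   out-of-sample squared correlation) and summary attributes.
#' @export
train_test_shrinkage_experiment <- function(h2_true = 0.32, n_train = 1500L,
                                            n_test = 300L, B = 3000L,
                                            n_splits = 5L,
                                            prior = prior_spec(),
                                            n_chains = 2L,
                                            n_iterations = 3000L,
                                            n_burnin = 1000L, thin = 5L,
                                            seed = 1L) {
  set.seed(seed)
  ntot <- n_train + n_test
  X <- matrix(stats::rnorm(ntot * B), ntot, B)
  rows <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(seed + 17L * s)
    idx <- sample.int(ntot, n_train)
    Xtr <- .standardize_cols(X[idx, , drop = FALSE])
    Xts <- .standardize_cols(X[-idx, , drop = FALSE])
    beta <- stats::rnorm(B, sd = sqrt(h2_true / B))
    Ytr <- simulate_outcome(Xtr, beta, h2_true)
    Yts <- simulate_outcome(Xts, beta, h2_true)
    dat <- model_data(Xtr, as.numeric(Ytr), check_standardized = FALSE)
    draws <- run_mcmc(dat, prior, mcmc_config(
      n_iterations = n_iterations, n_burnin = n_burnin, thin = thin,
      n_chains = n_chains, seed = seed + 17L * s + 1L, store_beta = TRUE))
    coef <- trained_coefficients(draws)
    h2_in <- stats::median(pool_chains(draws)$h2)
    h2_out <- out_of_sample_h2(Xts, as.numeric(Yts), coef)
    rows[[s]] <- data.frame(split = s, h2_in = h2_in, h2_out = h2_out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "h2_true") <- h2_true
  attr(out, "h2_in_median") <- stats::median(out$h2_in)
  attr(out, "h2_out_median") <- stats::median(out$h2_out)
  class(out) <- c("annovc_shrinkage", "data.frame")
  out
}
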