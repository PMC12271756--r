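test_that("Fisher z transform matches atanh, is odd, clips near the poles", {
  expect_identical(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
  expect_error(fisher_z(1.01), "\\[-1, 1\\]")
})

test_that("edge vectorization follows row-major upper-triangle order", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  ef <- build_edge_features(m, node_ids = c("a", "b", "c"))
  expect_equal(ef$edge_ids, c("a-b", "a-c", "b-c"))
  expect_equal(drop(ef$values), c(fisher_z(0.5), 0, 0))

  # P nodes -> P(P-1)/2 edges; identity matrices -> all-zero features
  P <- 352
  ef2 <- build_edge_features(diag(P))
  expect_equal(length(ef2$edge_ids), 61776L)
  expect_true(all(ef2$values == 0))
})

test_that("edge vectorization rejects malformed matrices and round-trips", {
  bad <- matrix(c(1, 0.2, 0.4, 1), 2, 2)
  expect_error(build_edge_features(bad), "symmetric")
  bad2 <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  expect_error(build_edge_features(bad2), "diagonal")

  set.seed(1)
  cm <- stats::cor(matrix(rnorm(40 * 6), 40, 6))
  ef <- build_edge_features(cm)
  expect_equal(edges_to_matrix(ef, 1), cm, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("within-network annotations mark edges with both endpoints inside", {
  m <- diag(4)
  ef <- build_edge_features(m, node_ids = c("n1", "n2", "n3", "n4"))
  labels <- data.frame(node_id = paste0("n", 1:4),
                       network = c("A", "A", "B", "None"))
  zA <- build_within_network_annotation(ef, labels, "A")
  # edges: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4); only (1,2) is within A
  expect_equal(zA, c(1, 0, 0, 0, 0, 0))
  expect_error(build_within_network_annotation(ef, labels, "Q"), "unknown")

  # all nodes unlabeled: None-None column is all ones, named columns all zero
  lab_none <- data.frame(node_id = paste0("n", 1:4), network = "None")
  expect_equal(build_within_network_annotation(ef, lab_none, "None"),
               rep(1, 6))
  Z <- build_annotation_matrix(ef, labels)
  expect_equal(colnames(Z), c("A-A", "B-B", "None-None"))
  expect_true(all(rowSums(Z) <= 1))
})

test_that("a 41-node network yields choose(41, 2) within-network edges", {
  P <- 352
  ef <- build_edge_features(diag(P))
  labels <- data.frame(node_id = ef$node_ids,
                       network = c(rep("DMN", 41), rep("None", P - 41)))
  z <- build_within_network_annotation(ef, labels, "DMN")
  expect_equal(sum(z), choose(41, 2))
  expect_equal(round(100 * sum(z) / length(z), 2), 1.33)
})

test_that("disjoint node labels give disjoint annotation columns partitioning the edges", {
  set.seed(2)
  P <- 20
  ef <- build_edge_features(diag(P))
  labels <- data.frame(node_id = ef$node_ids,
                       network = sample(c("A", "B", "C", "None"), P,
                                        replace = TRUE))
  Z <- build_annotation_matrix(ef, labels)
  expect_true(all(rowSums(Z) <= 1))
  # within-network + between/mixed edges account for every edge
  between <- sum(rowSums(Z) == 0)
  expect_equal(sum(colSums(Z)) + between, choose(P, 2))
})

test_that("residualization projects out covariates", {
  set.seed(4)
  n <- 120
  age <- rnorm(n, 120, 10)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  covs <- data.frame(age = age, sex = sex)
  y <- 2 * age + rnorm(n)
  r <- residualize(y, covs)
  expect_lt(abs(stats::cor(r, age)), 1e-10)

  # intercept only is centering
  expect_equal(residualize(y, data.frame(int = rep(1, n))[, 0, drop = FALSE]
               ), y - mean(y), tolerance = 1e-10)

  # matrix input: residuals orthogonal to the covariate span
  Xm <- matrix(rnorm(n * 5), n, 5)
  R <- residualize(Xm, covs)
  C <- stats::model.matrix(~ age + sex, covs)
  expect_lt(max(abs(crossprod(C, R))) / n, 1e-8)

  # already-orthogonal columns are unchanged
  orth <- residualize(Xm[, 1], covs)
  expect_equal(residualize(orth, covs), orth, tolerance = 1e-10)

  expect_error(residualize(y, cbind(a = age, b = 2 * age)), "rank deficient")
})

test_that("residualize-then-standardize is invariant to affine covariate changes", {
  set.seed(9)
  n <- 80
  covs <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)
  a <- standardize(residualize(y, covs))$values
  b <- standardize(residualize(y, 3 * covs + 7))$values
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("standardization records reusable moments and names offending columns", {
  set.seed(6)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc <- standardize(X)
  expect_equal(colMeans(sc$values), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(sc$values, 2, stats::sd), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  # applying the stored parameters to the training data reproduces it
  expect_equal(apply_standardization(X, sc), sc$values, ignore_attr = TRUE)

  X[, 2] <- 5
  expect_error(standardize(X), "b")
})

test_that("model data validates dimensions, missingness and standardization", {
  X <- std_cols(matrix(rnorm(40 * 6), 40, 6))
  Y <- std_vec(rnorm(40))
  expect_s3_class(model_data(X, Y), "annovc_data")
  expect_error(model_data(X, Y[-1]), "nrow")
  expect_error(model_data(X, Y, Z = matrix(0, 5, 1)), "one row per feature")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(model_data(Xb, Y), "missing")
  expect_error(model_data(X * 3, Y), "not standardized")
  expect_error(model_data(X, Y + 2), "not standardized")
})

test_that("delimited and RDS loaders round-trip a data set", {
  set.seed(8)
  X <- std_cols(matrix(rnorm(25 * 4), 25, 4))
  colnames(X) <- paste0("e", 1:4)
  Y <- std_vec(rnorm(25))
  Z <- simulate_annotations(4, 1, 0.5)
  td <- withr::local_tempdir()
  xf <- file.path(td, "x.csv")
  yf <- file.path(td, "y.csv")
  zf <- file.path(td, "z.csv")
  utils::write.csv(data.frame(id = 1:25, X, check.names = FALSE), xf,
                   row.names = FALSE)
  utils::write.csv(data.frame(y = Y), yf, row.names = FALSE)
  utils::write.csv(data.frame(feature = colnames(X), Z, check.names = FALSE),
                   zf, row.names = FALSE)
  d <- read_model_data(xf, yf, zf)
  expect_equal(unname(d$X), unname(X))
  expect_equal(d$Y, Y)
  expect_equal(d$M, 1L)

  rf <- file.path(td, "d.rds")
  saveRDS(list(X = X, Y = Y, Z = Z, feature_ids = colnames(X),
               annotation_names = "A1"), rf)
  d2 <- read_model_data(rf)
  expect_equal(d2$annotation_names, "A1")
  expect_equal(d2$B, 4L)
})
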