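#' Extract trained coefficients for prediction
#'
#' Builds the point estimate of the effect vector used for polyvertex
#' scoring. The default is the per-feature pooled posterior median (requires
#' stored beta draws); the posterior mean is always available from the
#' running accumulator.
#'
#' @param draws an `annovc_draws` object.
#' @param estimate `"median"` (default) or `"mean"`.
#' @param feature_ids feature identifiers; defaults to the ones carried by
#'   the fitted data, else `"f1" ... "fB"`.
#' @return An object of class `annovc_coef`: list with `beta_hat`,
#'   `feature_ids`, `estimate`, `h2_summary` and `annotation_names`.
#' @export
trained_coefficients <- function(draws, estimate = c("median", "mean"),
                                 feature_ids = NULL) {
  stopifnot(inherits(draws, "annovc_draws"))
  estimate <- match.arg(estimate)
  if (is.null(feature_ids)) {
    feature_ids <- draws$feature_ids
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(draws$B))
  }
  if (length(feature_ids) != draws$B) {
    stop("'feature_ids' must have length B = ", draws$B)
  }
  beta_hat <- if (estimate == "median") {
    if (is.null(draws$beta)) {
      stop("beta draws were not stored; rerun with store_beta = TRUE or use ",
           "estimate = \"mean\"")
    }
    pooled <- pool_chains(draws)$beta
    vapply(seq_len(draws$B), function(k) stats::median(pooled[, k]),
           numeric(1))
  } else {
    colMeans(draws$beta_mean)
  }
  pooled_h2 <- pool_chains(draws)$h2
  structure(
    list(beta_hat = as.numeric(beta_hat), feature_ids = feature_ids,
         estimate = estimate,
         h2_summary = c(median = stats::median(pooled_h2), .ci(pooled_h2)),
         annotation_names = draws$annotation_names),
    class = "annovc_coef"
  )
}

#' @export
print.annovc_coef <- function(x, ...) {
  cat(sprintf(
    "annovc_coef: %d features, %s point estimate, training h2 median %.3f\n",
    length(x$beta_hat), x$estimate, x$h2_summary[["median"]]))
  invisible(x)
}

.align_features <- function(X_new, coef, feature_ids) {
  if (is.null(feature_ids)) {
    stop("'X_new' carries no feature IDs; supply 'feature_ids' so features ",
         "can be aligned by identity rather than position")
  }
  if (length(feature_ids) != ncol(X_new)) {
    stop("'feature_ids' must have one entry per column of 'X_new'")
  }
  missing <- setdiff(coef$feature_ids, feature_ids)
  extra <- setdiff(feature_ids, coef$feature_ids)
  if (length(missing) || length(extra)) {
    stop("feature mismatch between coefficients and new data; missing: ",
         if (length(missing)) paste(utils::head(missing, 5), collapse = ", ")
         else "(none)",
         "; extra: ",
         if (length(extra)) paste(utils::head(extra, 5), collapse = ", ")
         else "(none)")
  }
  X_new[, match(coef$feature_ids, feature_ids), drop = FALSE]
}

#' Polyvertex scores
#'
#' The linear predictor `X_new %*% beta_hat` on a new cohort, the imaging
#' analogue of a polygenic score. Features are aligned by ID, never by
#' position; any missing or extra feature is an error.
#'
#' @param X_new participants x features matrix of standardized features for
#'   the new cohort.
#' @param coef an [trained_coefficients()] object.
#' @param feature_ids feature IDs of the columns of `X_new`; defaults to
#'   `colnames(X_new)`.
#' @return Numeric score vector, one per row of `X_new`.
#' @export
polyvertex_score <- function(X_new, coef, feature_ids = colnames(X_new)) {
  stopifnot(inherits(coef, "annovc_coef"))
  X_new <- as.matrix(X_new)
  Xa <- .align_features(X_new, coef, feature_ids)
  drop(Xa %*% coef$beta_hat)
}

#' Incremental variance explained by a polyvertex score
#'
#' Fits least squares of the outcome on the covariates alone and on the
#' covariates plus the polyvertex score, and reports the difference in
#' (plain, unadjusted) coefficients of determination.
#'
#' @param Y_new outcome vector for the new cohort.
#' @param pvs polyvertex scores from [polyvertex_score()].
#' @param covariates optional participants x q covariate matrix or data
#'   frame (an intercept is always included).
#' @return An object of class `annovc_prediction`: list with `incremental_r2`,
#'   `full_r2`, `covariate_r2` and `pvs`.
#' @export
incremental_r2 <- function(Y_new, pvs, covariates = NULL) {
  Y_new <- as.numeric(Y_new)
  if (anyNA(Y_new) || anyNA(pvs)) stop("missing values are not allowed")
  if (length(pvs) != length(Y_new)) stop("'pvs' and 'Y_new' lengths differ")
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    C <- matrix(1, length(Y_new), 1L)
  } else {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (qr(C)$rank < ncol(C)) stop("covariates are rank deficient")
  }
  r2 <- function(M) {
    fit <- stats::lm.fit(M, Y_new)
    1 - sum(fit$residuals^2) / sum((Y_new - mean(Y_new))^2)
  }
  full <- cbind(C, pvs = pvs)
  if (qr(full)$rank < ncol(full)) {
    stop("the polyvertex score is collinear with the covariates")
  }
  cov_r2 <- r2(C)
  full_r2 <- r2(full)
  structure(list(incremental_r2 = full_r2 - cov_r2, full_r2 = full_r2,
                 covariate_r2 = cov_r2, pvs = pvs),
            class = "annovc_prediction")
}

#' @export
print.annovc_prediction <- function(x, ...) {
  cat(sprintf(
    "annovc_prediction: incremental R2 = %.4f (full %.4f, covariates %.4f)\n",
    x$incremental_r2, x$full_r2, x$covariate_r2))
  invisible(x)
}

#' Out-of-sample h2 estimate
#'
#' The squared Pearson correlation between the polyvertex score
#' `X_test %*% beta_hat` and the test phenotype: the out-of-sample estimate
#' of variance explained, which approaches h2 only in the limit of an
#' infinitely large training sample and otherwise falls below the in-sample
#' estimate (shrinkage).
#'
#' @param X_test participants x features test design.
#' @param Y_test test phenotype vector.
#' @param coef an [trained_coefficients()] object.
#' @param feature_ids feature IDs for `X_test` columns; defaults to
#'   `colnames(X_test)`, or positional alignment when both sides carry no
#'   IDs is refused.
#' @return Scalar squared correlation.
#' @export
out_of_sample_h2 <- function(X_test, Y_test, coef,
                             feature_ids = colnames(X_test)) {
  stopifnot(inherits(coef, "annovc_coef"))
  X_test <- as.matrix(X_test)
  if (is.null(feature_ids) && identical(coef$feature_ids,
                                        paste0("f", seq_len(ncol(X_test))))) {
    feature_ids <- coef$feature_ids
  }
  pvs <- polyvertex_score(X_test, coef, feature_ids)
  if (stats::sd(pvs) == 0) {
    stop("polyvertex score has zero variance; cannot correlate with the outcome")
  }
  stats::cor(pvs, as.numeric(Y_test))^2
}
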