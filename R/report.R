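#' Pool draws across chains
#'
#' Concatenates the post-burn-in, thinned draws of all chains ("intermixed"
#' chains) per parameter, the form in which medians and percentile credible
#' intervals are reported.
#'
#' @param draws an `annovc_draws` object from [run_mcmc()].
#' @return List with `h2` (vector), `alpha` (draws x M matrix), `r2`
#'   (vector) and, when stored, `beta` (draws x B matrix).
#' @export
pool_chains <- function(draws) {
  stopifnot(inherits(draws, "annovc_draws"))
  nc <- nrow(draws$h2)
  L <- draws$kept
  out <- list(
    h2 = as.vector(t(draws$h2)),
    alpha = if (draws$M > 0L) {
      matrix(aperm(draws$alpha, c(2, 1, 3)), nc * L, draws$M)
    } else matrix(0, nc * L, 0L),
    r2 = as.vector(t(draws$r2))
  )
  if (!is.null(draws$beta)) {
    out$beta <- matrix(aperm(draws$beta, c(2, 1, 3)), nc * L, draws$B)
  }
  out
}

.ci <- function(x, level = 0.95) {
  stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

#' Posterior summaries
#'
#' Medians and equal-tailed 95% percentile credible intervals per parameter,
#' pooled across chains, plus the per-annotation enrichment ratio `exp(alpha)`
#' obtained by exponentiating the alpha interval endpoints (a monotone
#' transform, so it agrees with percentiles of the exponentiated draws up to
#' interpolation error). Percentiles use linear interpolation
#' between order statistics (R quantile type 7); the convention is recorded
#' in the `"quantile_type"` attribute.
#'
#' @param draws an `annovc_draws` object, or a list as returned by
#'   [pool_chains()].
#' @param level credible level (default 0.95).
#' @param min_draws minimum pooled draws required.
#' @return An object of class `annovc_summary`: a data frame with columns
#'   `parameter`, `median`, `lower`, `upper`, `mean` plus, for annotation
#'   rows, `enrichment`, `enrichment_lower`, `enrichment_upper`, `flag`.
#' @export
summarize_draws <- function(draws, level = 0.95, min_draws = 40L) {
  pooled <- if (inherits(draws, "annovc_draws")) pool_chains(draws) else draws
  anames <- if (inherits(draws, "annovc_draws") &&
                !is.null(draws$annotation_names)) {
    draws$annotation_names
  } else if (ncol(pooled$alpha)) {
    paste0("alpha", seq_len(ncol(pooled$alpha)))
  } else character(0)
  if (length(pooled$h2) < min_draws) {
    stop("too few pooled draws (", length(pooled$h2), " < ", min_draws,
         ") for stable interval summaries")
  }
  summ_one <- function(x, name) {
    ci <- .ci(x, level)
    data.frame(parameter = name, median = stats::median(x),
               lower = ci[1], upper = ci[2], mean = mean(x))
  }
  rows <- list(summ_one(pooled$h2, "h2"), summ_one(pooled$r2, "R2"))
  M <- ncol(pooled$alpha)
  for (m in seq_len(M)) {
    rows[[2L + m]] <- summ_one(pooled$alpha[, m], anames[m])
  }
  out <- do.call(rbind, rows)
  out$enrichment <- NA_real_
  out$enrichment_lower <- NA_real_
  out$enrichment_upper <- NA_real_
  out$flag <- NA_character_
  if (M > 0L) {
    i <- 2L + seq_len(M)
    out$enrichment[i] <- exp(out$median[i])
    out$enrichment_lower[i] <- exp(out$lower[i])
    out$enrichment_upper[i] <- exp(out$upper[i])
    out$flag[i] <- significance_flag(out$lower[i], out$upper[i])
  }
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "quantile_type") <- 7L
  attr(out, "n_draws") <- length(pooled$h2)
  class(out) <- c("annovc_summary", "data.frame")
  out
}

#' @export
print.annovc_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summaries (%d pooled draws, %.0f%% equal-tailed CIs)\n",
              attr(x, "n_draws"), 100 * attr(x, "level")))
  df <- as.data.frame(x)
  df$median <- round(df$median, digits)
  df$lower <- round(df$lower, digits)
  df$upper <- round(df$upper, digits)
  df$mean <- round(df$mean, digits)
  df$enrichment <- round(df$enrichment, digits)
  df$enrichment_lower <- round(df$enrichment_lower, digits)
  df$enrichment_upper <- round(df$enrichment_upper, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enrichment flag from a credible interval
#'
#' An annotation is flagged `"enriched"` when its 95% CI lies entirely above
#' zero, `"depleted"` when entirely below, and `"not-enriched"` when the
#' interval straddles zero (nominal intervals; no multiplicity correction is
#' applied across annotations).
#'
#' @param lower,upper credible-interval endpoints (vectorized).
#' @return Character vector.
#' @export
#' @examples
#' significance_flag(0.07, 0.27)   # "enriched"
#' significance_flag(-0.27, 0.32)  # "not-enriched"
significance_flag <- function(lower, upper) {
  if (any(lower > upper)) stop("'lower' must not exceed 'upper'")
  ifelse(lower > 0, "enriched", ifelse(upper < 0, "depleted", "not-enriched"))
}

#' Score credible-interval coverage against generating values
#'
#' For simulation studies: checks whether the pooled and the per-chain 95%
#' credible intervals contain the generating h2 and annotation weights, and
#' computes the per-feature coverage rate of beta (the fraction of features
#' whose interval contains the true effect), both from pooled draws and
#' averaged over per-chain intervals.
#'
#' @param draws an `annovc_draws` object with stored beta draws (for beta
#'   coverage).
#' @param truth list with elements `h2` (scalar), `alpha` (length-M vector,
#'   optional) and `beta` (length-B vector, optional).
#' @param level credible level.
#' @return List with `pooled_containment` (named logical), `chain_containment`
#'   (named integer counts out of the number of chains), `beta_coverage`
#'   (pooled), `beta_coverage_by_chain` (vector) and `n_chains`.
#' @export
evaluate_coverage <- function(draws, truth, level = 0.95) {
  stopifnot(inherits(draws, "annovc_draws"))
  nc <- nrow(draws$h2)
  pooled <- pool_chains(draws)
  lo <- (1 - level) / 2
  hi <- 1 - lo

  params <- list(h2 = list(pool = pooled$h2,
                           chain = function(ch) draws$h2[ch, ],
                           true = truth$h2))
  if (!is.null(truth$alpha) && draws$M > 0L) {
    for (m in seq_len(min(draws$M, length(truth$alpha)))) {
      params[[paste0("alpha", m)]] <- local({
        mm <- m
        list(pool = pooled$alpha[, mm],
             chain = function(ch) draws$alpha[ch, , mm],
             true = truth$alpha[mm])
      })
    }
  }
  pooled_cont <- vapply(params, function(p) {
    ci <- stats::quantile(p$pool, c(lo, hi), names = FALSE)
    p$true >= ci[1] && p$true <= ci[2]
  }, logical(1))
  chain_cont <- vapply(params, function(p) {
    sum(vapply(seq_len(nc), function(ch) {
      ci <- stats::quantile(p$chain(ch), c(lo, hi), names = FALSE)
      p$true >= ci[1] && p$true <= ci[2]
    }, logical(1)))
  }, integer(1))

  beta_cov <- NA_real_
  beta_cov_chain <- rep(NA_real_, nc)
  if (!is.null(truth$beta) && !is.null(draws$beta)) {
    beta_cov <- .beta_coverage(pooled$beta, truth$beta, lo, hi)
    for (ch in seq_len(nc)) {
      beta_cov_chain[ch] <- .beta_coverage(draws$beta[ch, , ], truth$beta,
                                           lo, hi)
    }
  }
  list(pooled_containment = pooled_cont, chain_containment = chain_cont,
       beta_coverage = beta_cov, beta_coverage_by_chain = beta_cov_chain,
       n_chains = nc)
}

# fraction of features whose [lo, hi] percentile interval of draws (rows)
# contains the true value
.beta_coverage <- function(draw_mat, beta_true, lo, hi) {
  B <- ncol(draw_mat)
  hits <- vapply(seq_len(B), function(k) {
    ci <- stats::quantile(draw_mat[, k], c(lo, hi), names = FALSE)
    beta_true[k] >= ci[1] && beta_true[k] <= ci[2]
  }, logical(1))
  mean(hits)
}

#' Write a summary table to a delimited file
#'
#' One row per annotation in the layout of a published enrichment table:
#' annotation name, alpha median (CI), h2 median (CI), R2 median (CI),
#' enrichment ratio (CI) and the enrichment flag.
#'
#' @param summary an `annovc_summary` object.
#' @param file output path (comma-separated).
#' @return The written data frame, invisibly.
#' @export
write_summary_table <- function(summary, file) {
  stopifnot(inherits(summary, "annovc_summary"))
  fmt <- function(i) sprintf("%.2f (%.2f,%.2f)", summary$median[i],
                             summary$lower[i], summary$upper[i])
  h2_i <- which(summary$parameter == "h2")
  r2_i <- which(summary$parameter == "R2")
  ann_i <- setdiff(seq_len(nrow(summary)), c(h2_i, r2_i))
  df <- data.frame(
    annotation = if (length(ann_i)) summary$parameter[ann_i] else "(none)",
    alpha = if (length(ann_i)) vapply(ann_i, fmt, "") else NA_character_,
    h2 = fmt(h2_i),
    R2 = fmt(r2_i),
    enrichment = if (length(ann_i)) {
      sprintf("%.2f (%.2f,%.2f)", summary$enrichment[ann_i],
              summary$enrichment_lower[ann_i], summary$enrichment_upper[ann_i])
    } else NA_character_,
    flag = if (length(ann_i)) summary$flag[ann_i] else NA_character_
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
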