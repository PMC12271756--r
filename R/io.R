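#' Persist chain output
#'
#' Writes the posterior draws to a directory: one RDS container per
#' parameter (`h2.rds`, `alpha.rds`, `r2.rds`, `beta_mean.rds`, and
#' `beta.rds` when stored), a delimited posterior summary table
#' (`summary.csv`) and a plain-text key-value run manifest (`manifest.txt`)
#' recording the schedule, seed, dimensions and package version.
#'
#' @param draws an `annovc_draws` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "annovc_draws"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(draws$h2, file.path(dir, "h2.rds"))
  saveRDS(draws$alpha, file.path(dir, "alpha.rds"))
  saveRDS(draws$r2, file.path(dir, "r2.rds"))
  saveRDS(draws$beta_mean, file.path(dir, "beta_mean.rds"))
  if (!is.null(draws$beta)) saveRDS(draws$beta, file.path(dir, "beta.rds"))
  saveRDS(draws[setdiff(names(draws), c("h2", "alpha", "r2", "beta",
                                        "beta_mean"))],
          file.path(dir, "meta.rds"))
  utils::write.csv(as.data.frame(summarize_draws(draws)),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  cfg <- draws$config
  manifest <- c(
    paste0("package: annovc ",
           as.character(utils::packageVersion("annovc"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("n_iterations: ", cfg$n_iterations),
    paste0("n_burnin: ", cfg$n_burnin),
    paste0("thin: ", cfg$thin),
    paste0("n_chains: ", cfg$n_chains),
    paste0("seed: ", cfg$seed),
    paste0("likelihood_power: ", cfg$likelihood_power),
    paste0("n: ", draws$n),
    paste0("B: ", draws$B),
    paste0("M: ", draws$M),
    paste0("prior_a: ", draws$prior$a),
    paste0("prior_d: ", draws$prior$d),
    paste0("prior_sigma_alpha_sq: ", draws$prior$sigma_alpha_sq)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Reload persisted chain output
#'
#' @param dir directory written by [save_draws()].
#' @return An `annovc_draws` object.
#' @export
load_draws <- function(dir) {
  meta <- readRDS(file.path(dir, "meta.rds"))
  out <- c(
    list(h2 = readRDS(file.path(dir, "h2.rds")),
         alpha = readRDS(file.path(dir, "alpha.rds")),
         r2 = readRDS(file.path(dir, "r2.rds")),
         beta = if (file.exists(file.path(dir, "beta.rds"))) {
           readRDS(file.path(dir, "beta.rds"))
         } else NULL,
         beta_mean = readRDS(file.path(dir, "beta_mean.rds"))),
    meta
  )
  class(out) <- "annovc_draws"
  out
}
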