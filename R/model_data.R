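#' Assemble a model data set
#'
#' Bundles the standardized design matrix of imaging-derived features, the
#' standardized phenotype and an optional feature annotation matrix into the
#' container used by every fitting and simulation function in the package.
#'
#' The model assumes that `Y` and each column of `X` have been standardized
#' (mean zero, unit variance); [standardize()] and [residualize()] prepare raw
#' inputs. Standardization is checked on construction because an
#' unstandardized design silently breaks the variance-components
#' interpretation of h2.
#'
#' @param X numeric matrix, participants x features. Column names, when
#'   present, are used as feature IDs.
#' @param Y numeric vector of length `nrow(X)`; the phenotype.
#' @param Z optional numeric matrix, features x annotations (binary or
#'   continuous annotation values). Column names are annotation names.
#' @param check_standardized if `TRUE` (default), verify that `Y` and the
#'   columns of `X` have mean 0 and unit variance within `tol`.
#' @param tol tolerance for the standardization check.
#'
#' @return An object of class `annovc_data`: a list with elements `X`, `Y`,
#'   `Z`, `n`, `B`, `M`, `feature_ids`, `annotation_names`.
#' @export
#' @examples
#' X <- scale(matrix(rnorm(50 * 8), 50, 8))[, ] * sqrt(50 / 49)
#' X <- apply(X, 2, function(x) (x - mean(x)) / stats::sd(x))
#' Y <- (rnorm(50))
#' d <- model_data(X, (Y - mean(Y)) / stats::sd(Y))
#' d$B
model_data <- function(X, Y, Z = NULL, check_standardized = TRUE, tol = 1e-4) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  if (!is.numeric(X)) stop("'X' must be a numeric matrix")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed in 'X' or 'Y'")
  if (length(Y) != nrow(X)) {
    stop("length of 'Y' (", length(Y), ") must equal nrow(X) (", nrow(X), ")")
  }
  n <- nrow(X)
  B <- ncol(X)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (anyNA(Z)) stop("missing values are not allowed in 'Z'")
    if (nrow(Z) != B) {
      stop("'Z' must have one row per feature: nrow(Z) = ", nrow(Z),
           ", ncol(X) = ", B)
    }
  }
  if (check_standardized) {
    cm <- colMeans(X)
    cv <- .colVars(X, cm)
    bad <- abs(cm) > tol | abs(cv - 1) > sqrt(tol)
    if (any(bad)) {
      stop("columns of 'X' are not standardized (first offender: ",
           .feature_label(X, which(bad)[1]),
           "); use standardize() or set check_standardized = FALSE")
    }
    if (abs(mean(Y)) > tol || abs(stats::var(Y) - 1) > sqrt(tol)) {
      stop("'Y' is not standardized; use standardize() or set ",
           "check_standardized = FALSE")
    }
  }
  structure(
    list(
      X = X, Y = Y, Z = Z, n = n, B = B,
      M = if (is.null(Z)) 0L else ncol(Z),
      feature_ids = colnames(X),
      annotation_names = if (is.null(Z)) NULL else colnames(Z)
    ),
    class = "annovc_data"
  )
}

#' @export
print.annovc_data <- function(x, ...) {
  cat("annovc_data: n =", x$n, "participants, B =", x$B, "features, M =",
      x$M, "annotations\n")
  invisible(x)
}

.colVars <- function(X, cm = colMeans(X)) {
  colSums(sweep(X, 2L, cm)^2) / (nrow(X) - 1)
}

.feature_label <- function(X, j) {
  if (!is.null(colnames(X))) colnames(X)[j] else paste0("column ", j)
}

#' Read model data from files
#'
#' Loads the design matrix, phenotype and optional annotation matrix either
#' from delimited text files or from a single RDS container with named
#' elements `X`, `Y`, `Z`, `feature_ids`, `annotation_names`.
#'
#' Delimited layout: the design file has a header row of feature IDs and a
#' first column of participant IDs; the phenotype file has one column (with
#' header) of phenotype values in the same participant order; the annotation
#' file has a header row of annotation names and a first column of feature
#' IDs matching the design header.
#'
#' @param path path to an `.rds` container, or to the delimited design file.
#' @param y_file,z_file paths to phenotype and annotation files (delimited
#'   mode only; `z_file` optional).
#' @param sep field separator for delimited files; `","` or `"\t"`.
#' @param ... passed on to [model_data()] (e.g. `check_standardized`).
#' @return An `annovc_data` object.
#' @seealso [model_data()]
#' @export
read_model_data <- function(path, y_file = NULL, z_file = NULL, sep = ",",
                            ...) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    X <- as.matrix(obj$X)
    if (!is.null(obj$feature_ids)) colnames(X) <- obj$feature_ids
    Z <- obj$Z
    if (!is.null(Z)) {
      Z <- as.matrix(Z)
      if (!is.null(obj$annotation_names)) colnames(Z) <- obj$annotation_names
    }
    return(model_data(X, as.numeric(obj$Y), Z, ...))
  }
  if (is.null(y_file)) stop("'y_file' is required when reading delimited input")
  xt <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  X <- as.matrix(xt)
  yt <- utils::read.table(y_file, header = TRUE, sep = sep,
                          check.names = FALSE)
  Y <- as.numeric(yt[[ncol(yt)]])
  Z <- NULL
  if (!is.null(z_file)) {
    zt <- utils::read.table(z_file, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE)
    if (!identical(rownames(zt), colnames(X))) {
      zt <- zt[colnames(X), , drop = FALSE]
      if (anyNA(zt)) stop("annotation file feature IDs do not match design columns")
    }
    Z <- as.matrix(zt)
  }
  model_data(X, Y, Z, ...)
}
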