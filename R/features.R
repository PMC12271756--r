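#' Fisher z transform
#'
#' `atanh(r)`, the variance-stabilizing transform applied to Pearson
#' correlations before they enter the model as edge features. Correlations
#' with `|r| >= 1 - 1e-7` are clipped to `1 - 1e-7` in magnitude (the
#' transform is unbounded at +/-1) with a warning; `|r| > 1` is an error.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return `atanh` of the (possibly clipped) input.
#' @export
#' @examples
#' fisher_z(0.5)
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  clip <- 1 - 1e-7
  near <- abs(r) >= clip
  if (any(near, na.rm = TRUE)) {
    warning(sum(near, na.rm = TRUE),
            " correlation(s) with |r| >= 1 - 1e-7 clipped before transforming")
    r[which(near)] <- sign(r[which(near)]) * clip
  }
  atanh(r)
}

#' Vectorize node-by-node correlation matrices into edge features
#'
#' Converts per-participant symmetric correlation matrices into a
#' participants x edges matrix of Fisher-z connectivities. Edges are the
#' strict upper triangle in row-major order over the declared node order:
#' (1,2), (1,3), ..., (1,P), (2,3), ..., (P-1,P); a P-node parcellation
#' yields P(P-1)/2 edges. Edge IDs are `"nodeA-nodeB"` with A before B in
#' node order.
#'
#' @param mats a list of P x P symmetric numeric matrices with unit
#'   diagonals (one per participant) or a single such matrix; all must share
#'   the same node order.
#' @param node_ids node identifiers; defaults to the rownames of the first
#'   matrix, else `"n1" ... "nP"`.
#' @param tol tolerance for the symmetry and unit-diagonal checks.
#' @return An object of class `annovc_edges`: list with `values`
#'   (participants x edges Fisher-z matrix), `i`, `j` (1-based endpoint
#'   indices per edge), `edge_ids` and `node_ids`.
#' @export
build_edge_features <- function(mats, node_ids = NULL, tol = 1e-8) {
  if (is.matrix(mats)) mats <- list(mats)
  P <- nrow(mats[[1]])
  if (is.null(node_ids)) {
    node_ids <- rownames(mats[[1]])
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(P))
  }
  if (length(node_ids) != P) stop("'node_ids' must have one entry per node")
  i <- rep(seq_len(P - 1L), times = (P - 1L):1L)
  j <- unlist(lapply(seq_len(P - 1L), function(a) (a + 1L):P))
  nE <- length(i)
  values <- matrix(NA_real_, length(mats), nE)
  for (p in seq_along(mats)) {
    m <- as.matrix(mats[[p]])
    if (nrow(m) != P || ncol(m) != P) {
      stop("participant ", p, ": matrix dimensions differ from the first")
    }
    if (max(abs(m - t(m))) > tol) {
      stop("participant ", p, ": correlation matrix is not symmetric")
    }
    if (max(abs(diag(m) - 1)) > tol) {
      stop("participant ", p, ": correlation matrix diagonal is not 1")
    }
    values[p, ] <- fisher_z(m[cbind(i, j)])
  }
  structure(
    list(values = values, i = i, j = j,
         edge_ids = paste0(node_ids[i], "-", node_ids[j]),
         node_ids = node_ids),
    class = "annovc_edges"
  )
}

#' @export
print.annovc_edges <- function(x, ...) {
  cat(sprintf("annovc_edges: %d participant(s), %d nodes, %d edges\n",
              nrow(x$values), length(x$node_ids), length(x$edge_ids)))
  invisible(x)
}

#' Reconstruct a correlation matrix from edge features
#'
#' Inverts [build_edge_features()] for one participant: places the inverse
#' Fisher-z values back into a symmetric matrix with unit diagonal.
#'
#' @param edges an `annovc_edges` object.
#' @param participant row index into `edges$values`.
#' @return A P x P symmetric correlation matrix.
#' @export
edges_to_matrix <- function(edges, participant = 1L) {
  stopifnot(inherits(edges, "annovc_edges"))
  P <- length(edges$node_ids)
  m <- diag(P)
  r <- tanh(edges$values[participant, ])
  m[cbind(edges$i, edges$j)] <- r
  m[cbind(edges$j, edges$i)] <- r
  dimnames(m) <- list(edges$node_ids, edges$node_ids)
  m
}

.check_labels <- function(edges, labels) {
  if (!all(c("node_id", "network") %in% names(labels))) {
    stop("'labels' needs columns 'node_id' and 'network'")
  }
  if (anyDuplicated(labels$node_id)) stop("node IDs in 'labels' must be unique")
  missing <- setdiff(edges$node_ids, labels$node_id)
  if (length(missing)) {
    stop("edge endpoints absent from the label table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  labels$network[match(edges$node_ids, labels$node_id)]
}

#' Within-network edge annotation
#'
#' Builds one binary annotation column over edges: an edge is annotated when
#' both endpoints carry the queried network label. Querying `"None"` yields
#' the "None-None" category — edges whose two endpoints belong to no named
#' network.
#'
#' @param edges an `annovc_edges` object.
#' @param labels data frame with columns `node_id` and `network` (network
#'   name or `"None"` for unlabeled nodes).
#' @param network the network name to query.
#' @return A binary vector of length `length(edges$edge_ids)`.
#' @export
build_within_network_annotation <- function(edges, labels, network) {
  stopifnot(inherits(edges, "annovc_edges"))
  net <- .check_labels(edges, labels)
  known <- unique(c(labels$network, "None"))
  if (!network %in% known) {
    stop("unknown network '", network, "'; known: ",
         paste(sort(known), collapse = ", "))
  }
  as.numeric(net[edges$i] == network & net[edges$j] == network)
}

#' Within-network annotation matrix
#'
#' One column per queried network (default: every named network in the label
#' table plus the "None-None" category), named `"<network>-<network>"`.
#'
#' @inheritParams build_within_network_annotation
#' @param networks networks to include; defaults to all labels plus "None".
#' @return An edges x networks binary matrix.
#' @export
build_annotation_matrix <- function(edges, labels, networks = NULL) {
  if (is.null(networks)) {
    networks <- c(sort(setdiff(unique(labels$network), "None")), "None")
  }
  Z <- vapply(networks,
              function(nw) build_within_network_annotation(edges, labels, nw),
              numeric(length(edges$edge_ids)))
  colnames(Z) <- paste0(networks, "-", networks)
  Z
}

#' Residualize on covariates
#'
#' Least-squares residuals of each column of `x` on the covariates, with an
#' intercept always prepended. Categorical covariates are expanded via
#' reference-level indicator coding. Residuals are orthogonal to the
#' covariate span by construction.
#'
#' @param x numeric matrix or vector (participants in rows).
#' @param covariates participants x q matrix or data frame.
#' @return Residuals with the same shape as `x`.
#' @export
residualize <- function(x, covariates) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  covariates <- as.data.frame(covariates)
  C <- if (ncol(covariates) == 0L) {
    matrix(1, nrow(covariates), 1L)  # intercept only: plain centering
  } else {
    stats::model.matrix(~ ., data = covariates)
  }
  if (nrow(C) != nrow(xm)) stop("covariates and 'x' disagree on participants")
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariates are rank deficient")
  res <- qr.resid(qrC, xm)
  if (vec) drop(res) else res
}

#' Standardize columns, recording the transformation
#'
#' Centers and scales each column to mean 0 and unit variance (denominator
#' n - 1) and retains the moments so the same transformation can be applied
#' to held-out data via [apply_standardization()].
#'
#' @param x numeric matrix or vector.
#' @return An object of class `annovc_scaler`: list with `values`
#'   (standardized copy), `center`, `scale`.
#' @export
standardize <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  center <- colMeans(xm)
  xc <- sweep(xm, 2L, center)
  scl <- sqrt(colSums(xc^2) / (nrow(xm) - 1))
  zero <- scl == 0
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(utils::head(.col_ids(xm, which(zero)), 5), collapse = ", "))
  }
  out <- sweep(xc, 2L, scl, "/")
  structure(list(values = if (vec) drop(out) else out,
                 center = center, scale = scl),
            class = "annovc_scaler")
}

.col_ids <- function(x, idx) {
  if (!is.null(colnames(x))) colnames(x)[idx] else paste0("column ", idx)
}

#' Apply a recorded standardization
#'
#' @param x new data with the same columns as the data that produced
#'   `scaler`.
#' @param scaler an `annovc_scaler` from [standardize()].
#' @return Standardized copy of `x` using the stored training moments.
#' @export
apply_standardization <- function(x, scaler) {
  stopifnot(inherits(scaler, "annovc_scaler"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  if (ncol(xm) != length(scaler$center)) {
    stop("'x' and the scaler disagree on the number of columns")
  }
  out <- sweep(sweep(xm, 2L, scaler$center), 2L, scaler$scale, "/")
  if (vec) drop(out) else out
}
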