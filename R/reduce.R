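# Dimensionality-reduction tracks: turn user data into a 3D point cloud.
#
# Three entry tracks mirror the kinds of data people want to color:
#   * reduce_highdim():     dense entity x feature matrices -> PCA + UMAP
#   * reduce_single_cell(): sparse/dense count matrices; genes are the
#                           entities to be colored, cells the features
#   * reduce_distance():    precomputed square distance matrices
# All tracks return a (name, x, y, z) tibble and are deterministic given
# their seed (UMAP runs single-threaded with a fixed seed).

.as_feature_matrix <- function(data, what = "data") {
  if (is.data.frame(data)) {
    nm <- as.character(data[[1L]])
    m <- as.matrix(data[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- nm
  } else if (is.matrix(data) || inherits(data, "Matrix")) {
    m <- data
    if (is.null(rownames(m))) rownames(m) <- paste0("e", seq_len(nrow(m)))
  } else {
    stop(what, " must be a data frame (first column = names) or a matrix",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop(what, " has duplicate entity names", call. = FALSE)
  if (!all(is.finite(if (inherits(m, "Matrix")) m@x else m))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  m
}

.check_n <- function(n, n_neighbors) {
  if (n <= 4L) {
    stop("too few entities (", n, "); at least 5 are needed for a 3D embedding",
         call. = FALSE)
  }
  min(n_neighbors, n - 1L)
}

.umap3 <- function(x, n_neighbors, seed) {
  emb <- uwot::umap(x, n_components = 3L, n_neighbors = n_neighbors,
                    n_threads = 1L, n_sgd_threads = 0L, seed = seed,
                    verbose = FALSE)
  unname(emb)
}

#' Reduce a high-dimensional feature matrix to a 3D point cloud
#'
#' The general-purpose track: centered PCA to at most `n_pcs` components
#' followed by UMAP to three dimensions.
#'
#' @param data Entities x features: a data frame whose first column holds
#'   entity names, or a numeric matrix with rownames.
#' @param n_pcs Number of principal components (capped at `min(n - 1, m)`).
#' @param n_neighbors UMAP neighborhood size.
#' @param seed Integer seed; the embedding is deterministic given it.
#' @return A tibble `(name, x, y, z)` in input row order.
#' @export
reduce_highdim <- function(data, n_pcs = 50L, n_neighbors = 15L, seed = 42L) {
  m <- .as_feature_matrix(data)
  n_neighbors <- .check_n(nrow(m), n_neighbors)
  if (all(apply(m, 2, stats::sd) < 1e-12)) {
    stop("feature matrix has no variance; nothing to embed", call. = FALSE)
  }
  k <- min(n_pcs, nrow(m) - 1L, ncol(m))
  scores <- stats::prcomp(m, rank. = k, center = TRUE, scale. = FALSE)$x
  emb <- .umap3(scores, n_neighbors, seed)
  .cloud_tibble(rownames(m), emb)
}

#' Reduce a single-cell count matrix to a 3D point cloud of genes
#'
#' The single-cell track colors genes by their expression profile across
#' cells. Counts are normalized per cell, `x' = log(1 + x * scale_factor /
#' cell_total)`, without centering or scaling genes, then reduced by
#' uncentered PCA and UMAP. Natural log is the default; see `log_base`.
#'
#' @param counts Nonnegative counts: a base or [Matrix::Matrix] sparse
#'   matrix, or a data frame whose first column holds names. Genes in rows
#'   by default; set `genes_in_rows = FALSE` for a cells x genes matrix,
#'   which is transposed internally.
#' @param scale_factor Per-cell library-size target (counts are rescaled to
#'   this total before the log).
#' @param n_pcs Number of components of the uncentered PCA.
#' @param n_neighbors UMAP neighborhood size (per gene).
#' @param seed Integer seed.
#' @param genes_in_rows Orientation of `counts`.
#' @param log_base Base of the log transform; `exp(1)` (natural log, the
#'   behavior of the standard log-normalization) or e.g. `2`.
#' @return A tibble `(name, x, y, z)`, one row per gene.
#' @export
reduce_single_cell <- function(counts, scale_factor = 1e4, n_pcs = 50L,
                               n_neighbors = 50L, seed = 42L,
                               genes_in_rows = TRUE, log_base = exp(1)) {
  m <- .as_feature_matrix(counts, "counts")
  if (!genes_in_rows) m <- Matrix::t(m)
  neg <- if (inherits(m, "Matrix")) length(m@x) && min(m@x) < 0 else min(m) < 0
  if (neg) stop("counts must be nonnegative", call. = FALSE)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts dropped",
            call. = FALSE)
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (ncol(m) < 2L) stop("fewer than 2 usable cells", call. = FALSE)
  n_neighbors <- .check_n(nrow(m), n_neighbors)

  norm <- lognormalize_counts(m, scale_factor = scale_factor,
                              log_base = log_base)

  k <- min(n_pcs, nrow(norm) - 1L, ncol(norm))
  # uncentered PCA: truncated SVD of the normalized matrix, genes as rows
  sv <- if (k < min(dim(norm)) / 3 && min(dim(norm)) > 10L) {
    irlba::irlba(norm, nv = k)
  } else {
    s <- svd(norm, nu = k, nv = 0L)
    list(u = s$u, d = s$d[seq_len(k)])
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  emb <- .umap3(scores, n_neighbors, seed)
  .cloud_tibble(rownames(m), emb)
}

#' Per-cell log-normalization of a count matrix
#'
#' `x' = log(1 + x * scale_factor / cell_total)` in base `log_base`
#' (natural log by default), with cells in columns. A zero count maps to
#' zero for any cell total, so sparsity is preserved.
#'
#' @param counts Nonnegative genes x cells matrix (base or sparse).
#' @param scale_factor Per-cell library-size target.
#' @param log_base Base of the log transform.
#' @return A dense genes x cells matrix of normalized values.
#' @export
lognormalize_counts <- function(counts, scale_factor = 1e4, log_base = exp(1)) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cells with zero total counts", call. = FALSE)
  norm <- as.matrix(counts %*% Matrix::Diagonal(x = scale_factor / totals))
  dimnames(norm) <- dimnames(counts)
  log1p(norm) / log(log_base)
}

#' Embed a precomputed distance matrix as a 3D point cloud
#'
#' Uses the matrix as a precomputed metric for UMAP.
#'
#' @param d A square, symmetric, nonnegative distance matrix with zero
#'   diagonal (matrix with dimnames, or data frame with a name column).
#' @param n_neighbors UMAP neighborhood size.
#' @param seed Integer seed.
#' @param symmetrize If `TRUE`, an asymmetric matrix is averaged with its
#'   transpose instead of raising an error.
#' @return A tibble `(name, x, y, z)` in input row order.
#' @export
reduce_distance <- function(d, n_neighbors = 15L, seed = 42L,
                            symmetrize = FALSE) {
  m <- .as_feature_matrix(d, "distance matrix")
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop("distance matrix must be square (got ", nrow(m), " x ", ncol(m), ")",
         call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    if (symmetrize) m <- (m + t(m)) / 2
    else stop("distance matrix is not symmetric (use symmetrize = TRUE to average)",
              call. = FALSE)
  }
  if (any(m < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (any(abs(diag(m)) > 1e-8)) stop("distance matrix diagonal must be zero", call. = FALSE)
  n_neighbors <- .check_n(nrow(m), n_neighbors)
  emb <- .umap3(stats::as.dist(m), n_neighbors, seed)
  .cloud_tibble(rownames(m), emb)
}
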