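# Synthetic datasets with known group structure, used for tests, demos and
# the end-to-end checks: if the pipeline works, entities from the same
# group must receive more similar colors than entities from different
# groups. Each generator is deterministic given its seed and returns the
# data plus the ground-truth labels.

.balanced_labels <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

#' Synthetic 3D cluster cloud
#'
#' `n` points in `k` spherical Gaussian clusters whose centers form an
#' equilateral simplex with side `separation * sigma` -- well-separated
#' clusters a 3D embedding step would produce.
#'
#' @param n Number of points (split as evenly as possible across clusters).
#' @param k Number of clusters.
#' @param separation Center separation in units of `sigma`.
#' @param sigma Within-cluster standard deviation per coordinate.
#' @param seed Integer seed.
#' @return A list: `data` (tibble `name, x, y, z`), `labels` (integer).
#' @export
synth_clusters3d <- function(n = 60L, k = 3L, separation = 10, sigma = 1,
                             seed = 42L) {
  stopifnot(n >= 12L, k >= 2L)
  side <- separation * sigma
  centers <- rbind(c(0, 0, 0),
                   c(side, 0, 0),
                   c(side / 2, side * sqrt(3) / 2, 0),
                   c(side / 2, side / (2 * sqrt(3)), side * sqrt(2 / 3)))
  stopifnot(k <= nrow(centers))
  labels <- .balanced_labels(n, k)
  old <- .save_seed(); set.seed(seed)
  pts <- centers[labels, , drop = FALSE] + matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  .restore_seed(old)
  list(data = .cloud_tibble(sprintf("p%03d", seq_len(n)), pts),
       labels = labels)
}

#' Synthetic high-dimensional cluster matrix
#'
#' `n` points in `k` Gaussian clusters in `dim` dimensions; cluster centers
#' are mutually `separation * sigma` apart.
#'
#' @inheritParams synth_clusters3d
#' @param dim Feature dimensionality.
#' @return A list: `data` (tibble with a `name` column and `dim` feature
#'   columns), `labels` (integer).
#' @export
synth_highdim_clusters <- function(n = 300L, dim = 50L, k = 3L,
                                   separation = 10, sigma = 1, seed = 42L) {
  stopifnot(n >= 12L, k >= 2L, dim >= k)
  # centers on scaled coordinate axes: pairwise distance = separation * sigma
  centers <- diag(separation * sigma / sqrt(2), k, dim)
  labels <- .balanced_labels(n, k)
  old <- .save_seed(); set.seed(seed)
  m <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dim, sd = sigma), n, dim)
  .restore_seed(old)
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(out) <- sprintf("f%02d", seq_len(dim))
  out <- dplyr::bind_cols(tibble::tibble(name = sprintf("p%03d", seq_len(n))), out)
  list(data = out, labels = labels)
}

#' Synthetic single-cell count matrix with gene modules
#'
#' Genes belong to one of `k` modules; genes in a module share a cell-loading
#' pattern (high expected expression in one block of cells, low elsewhere)
#' and counts are Poisson draws around it, giving a sparse nonnegative
#' integer matrix.
#'
#' @param n_genes Number of genes (the entities to be colored).
#' @param n_cells Number of cells.
#' @param k Number of gene modules (and matching cell blocks).
#' @param high,low Expected counts inside / outside a gene's module block.
#' @param seed Integer seed.
#' @return A list: `counts` (genes x cells sparse dgCMatrix with dimnames),
#'   `labels` (integer module of each gene).
#' @export
synth_sc_counts <- function(n_genes = 90L, n_cells = 60L, k = 3L,
                            high = 5, low = 0.2, seed = 42L) {
  stopifnot(n_genes >= 12L, n_cells >= k)
  gene_mod <- .balanced_labels(n_genes, k)
  cell_blk <- .balanced_labels(n_cells, k)
  mu <- matrix(low, n_genes, n_cells)
  for (j in seq_len(k)) mu[gene_mod == j, cell_blk == j] <- high
  old <- .save_seed(); set.seed(seed)
  counts <- matrix(stats::rpois(length(mu), mu), n_genes, n_cells)
  .restore_seed(old)
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("c%03d", seq_len(n_cells)))
  list(counts = Matrix::Matrix(counts, sparse = TRUE), labels = gene_mod)
}

#' Synthetic clique distance matrix
#'
#' A distance matrix over `n` entities in `k` cliques: small jittered
#' distances within a clique, large between cliques.
#'
#' @param n Number of entities.
#' @param k Number of cliques.
#' @param within,between Nominal within- and between-clique distances;
#'   each entry is jittered by up to 10% (symmetrically).
#' @param seed Integer seed.
#' @return A list: `dist` (n x n matrix with dimnames), `labels` (integer).
#' @export
synth_cliques_dist <- function(n = 60L, k = 3L, within = 0.1, between = 10,
                               seed = 42L) {
  stopifnot(n >= 12L, between > within, within > 0)
  labels <- .balanced_labels(n, k)
  base <- ifelse(outer(labels, labels, "=="), within, between)
  old <- .save_seed(); set.seed(seed)
  jit <- matrix(stats::runif(n * n, -0.1, 0.1), n, n)
  .restore_seed(old)
  jit <- (jit + t(jit)) / 2
  d <- base * (1 + jit)
  diag(d) <- 0
  dimnames(d) <- list(sprintf("e%03d", seq_len(n)), sprintf("e%03d", seq_len(n)))
  list(dist = d, labels = labels)
}

#' Write a synthetic fixture to disk
#'
#' Generates one of the synthetic datasets and writes it in the file format
#' its track consumes, plus a `<path>.labels.tsv` sidecar with the
#' ground-truth group labels. Identical `kind`, `n`, and `seed` give
#' byte-identical files.
#'
#' @param kind One of `"clusters3d"` (3-column TSV for the direct-3D track),
#'   `"highdim-clusters"` (dense TSV), `"sc-counts"` (Matrix Market `.mtx`
#'   with `<path>.rownames.txt` / `<path>.colnames.txt` sidecars), or
#'   `"cliques-dist"` (square TSV).
#' @param n Number of entities (genes for `"sc-counts"`).
#' @param seed Integer seed.
#' @param out_path Path of the main output file.
#' @return `out_path`, invisibly.
#' @export
generate_fixture <- function(kind = c("clusters3d", "highdim-clusters",
                                      "sc-counts", "cliques-dist"),
                             n = 60L, seed = 42L, out_path) {
  kind <- match.arg(kind)
  stopifnot(n >= 12L)
  if (kind == "clusters3d") {
    s <- synth_clusters3d(n = n, seed = seed)
    readr::write_tsv(s$data, out_path)
    labels <- tibble::tibble(name = s$data$name, label = s$labels)
  } else if (kind == "highdim-clusters") {
    s <- synth_highdim_clusters(n = n, seed = seed)
    readr::write_tsv(s$data, out_path)
    labels <- tibble::tibble(name = s$data$name, label = s$labels)
  } else if (kind == "sc-counts") {
    s <- synth_sc_counts(n_genes = n, seed = seed)
    Matrix::writeMM(s$counts, out_path)
    writeLines(rownames(s$counts), paste0(out_path, ".rownames.txt"))
    writeLines(colnames(s$counts), paste0(out_path, ".colnames.txt"))
    labels <- tibble::tibble(name = rownames(s$counts), label = s$labels)
  } else {
    s <- synth_cliques_dist(n = n, seed = seed)
    d <- tibble::as_tibble(as.data.frame(s$dist), .name_repair = "minimal")
    d <- dplyr::bind_cols(tibble::tibble(name = rownames(s$dist)), d)
    readr::write_tsv(d, out_path)
    labels <- tibble::tibble(name = rownames(s$dist), label = s$labels)
  }
  readr::write_tsv(labels, paste0(out_path, ".labels.tsv"))
  invisible(out_path)
}
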