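# File I/O and the track runner behind the command-line interface.
#
# Delimited files are CSV or TSV by extension; sparse counts are Matrix
# Market with sidecar row/column name files. The color table is written
# atomically (temp file then rename) so a failed run never leaves partial
# output.

.delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

.read_delim_named <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_delim(path, delim = .delim_for(path), show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) stop("failed to parse ", what, " '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L) stop(what, " '", path, "' needs a name column plus data columns",
                          call. = FALSE)
  bad <- which(!purrr::map_lgl(df[-1L], is.numeric))
  if (length(bad)) {
    stop(what, " '", path, "': non-numeric data column '", names(df[-1L])[bad[1]],
         "' (column ", bad[1] + 1L, ")", call. = FALSE)
  }
  df
}

#' Read an already-reduced 3D point cloud from CSV/TSV
#'
#' Expects a header row, an entity-name first column, and three coordinate
#' columns.
#'
#' @param path File path (`.csv` comma-delimited, otherwise tab).
#' @return A tibble `(name, x, y, z)`.
#' @export
read_point_cloud <- function(path) {
  df <- .read_delim_named(path, "3D point cloud")
  if (ncol(df) != 4L) {
    stop("3D point cloud '", path, "' must have exactly 1 name + 3 coordinate columns, got ",
         ncol(df), call. = FALSE)
  }
  cl <- .as_cloud(as.data.frame(df))
  .cloud_tibble(cl$names, cl$coords)
}

#' Read a dense feature or distance matrix from CSV/TSV
#'
#' Header row, entity-name first column, numeric data columns.
#'
#' @param path File path.
#' @param transpose If `TRUE`, the parsed matrix is transposed (data column
#'   names become the entity names).
#' @return A numeric matrix with rownames.
#' @export
read_feature_matrix <- function(path, transpose = FALSE) {
  df <- .read_delim_named(path, "feature matrix")
  m <- as.matrix(df[-1L])
  rownames(m) <- as.character(df[[1L]])
  if (transpose) m <- t(m)
  m
}

#' Read a sparse count matrix in Matrix Market format
#'
#' @param path Path to the `.mtx` file.
#' @param rownames_path,colnames_path Sidecar files with one name per line;
#'   default `<path>.rownames.txt` and `<path>.colnames.txt`.
#' @return A sparse `dgCMatrix` with dimnames.
#' @export
read_sparse_counts <- function(path,
                               rownames_path = paste0(path, ".rownames.txt"),
                               colnames_path = paste0(path, ".colnames.txt")) {
  for (p in c(path, rownames_path, colnames_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  rn <- readLines(rownames_path)
  cn <- readLines(colnames_path)
  if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
    stop("sidecar name files do not match matrix dimensions (",
         nrow(m), " x ", ncol(m), " vs ", length(rn), " / ", length(cn), ")",
         call. = FALSE)
  }
  dimnames(m) <- list(rn, cn)
  m
}

#' Write a color table as TSV
#'
#' Written to a temporary file in the target directory and renamed into
#' place, so no partial table is ever left behind. Numeric columns use the
#' shortest round-trip decimal representation: reading the file back
#' reproduces the in-memory table exactly.
#'
#' @param table A color-table tibble from [encode_colors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_color_table <- function(table, path) {
  tmp <- tempfile("colortable", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_tsv(table, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

#' Read a color table written by [write_color_table()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_color_table <- function(path) {
  # base read.delim parses doubles with strtod (correctly rounded), so the
  # shortest-round-trip representations written by write_color_table()
  # recover the original doubles bit for bit
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Run a full color-encoding track from file to file
#'
#' Reads the input in the track's format, reduces it to 3D (skipped for
#' `"direct3d"`), fits the cloud inside the displayable CIELAB gamut, and
#' writes the per-entity color table as TSV. All randomness (initial fit
#' rotations, UMAP) flows from `seed`.
#'
#' @param track `"single-cell"` (Matrix Market counts with name sidecars),
#'   `"highdim"` (dense CSV/TSV), `"distmatrix"` (square CSV/TSV), or
#'   `"direct3d"` (3-column CSV/TSV).
#' @param input_path Input file.
#' @param out_path Output TSV path for the color table.
#' @param weights Axis weights `(L, a, b)` for the fit objective.
#' @param n_starts Number of optimizer starts.
#' @param seed Integer seed.
#' @param format Color columns to write: `"both"`, `"hex"`, or `"lab"`.
#' @param clamp If `FALSE`, out-of-gamut points are an error.
#' @param transpose For `"single-cell"`: input is cells x genes; for
#'   `"highdim"`: transpose the parsed matrix.
#' @param save_fit Optional path: write the fit as JSON ([write_color_fit()]).
#' @param apply_fit Optional path: reuse a saved fit ([read_color_fit()])
#'   instead of optimizing, applying its transform to this input's 3D cloud.
#' @param n_neighbors UMAP neighborhood size (reduction tracks); `NULL` for
#'   the track default (50 for single-cell, 15 otherwise).
#' @param verbose Log per-stage progress and timing to stderr.
#' @return The color table, invisibly, with the fit in `attr(, "fit")`.
#' @export
run_track <- function(track = c("single-cell", "highdim", "distmatrix", "direct3d"),
                      input_path, out_path,
                      weights = c(1, 1, 1), n_starts = 25L, seed = 42L,
                      format = c("both", "hex", "lab"), clamp = TRUE,
                      transpose = FALSE, save_fit = NULL, apply_fit = NULL,
                      n_neighbors = NULL, verbose = FALSE) {
  track <- match.arg(track)
  format <- match.arg(format)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    say("[%s] %.2fs", label, proc.time()[["elapsed"]] - t0)
    out
  }

  cloud <- stage(paste0("read+reduce:", track), switch(
    track,
    "direct3d" = read_point_cloud(input_path),
    "highdim" = reduce_highdim(read_feature_matrix(input_path, transpose),
                               n_neighbors = n_neighbors %||% 15L, seed = seed),
    "distmatrix" = reduce_distance(read_feature_matrix(input_path),
                                   n_neighbors = n_neighbors %||% 15L, seed = seed),
    "single-cell" = reduce_single_cell(read_sparse_counts(input_path),
                                       genes_in_rows = !transpose,
                                       n_neighbors = n_neighbors %||% 50L,
                                       seed = seed)
  ))

  fit <- if (!is.null(apply_fit)) {
    stage("load-fit", read_color_fit(apply_fit))
  } else {
    stage("fit", fit_colors(cloud, weights = weights,
                            config = fit_config(n_starts = n_starts, seed = seed)))
  }

  table <- stage("encode", encode_colors(cloud, fit, format = format, clamp = clamp))
  say("[encode] %d point(s) clamped", attr(table, "n_clamped"))

  if (!is.null(save_fit)) write_color_fit(fit, save_fit)
  write_color_table(table, out_path)
  say("[write] %s (%d rows)", out_path, nrow(table))
  attr(table, "fit") <- fit
  invisible(table)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
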