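# Point-cloud geometry: validation, 3D convex hull, similarity transform.
#
# A point cloud is a data frame whose first column holds unique entity names
# and whose next three columns are finite coordinates. Internally clouds are
# n x 3 matrices with a names attribute.

.as_cloud <- function(data, what = "data") {
  if (is.matrix(data)) {
    if (ncol(data) != 3L) stop(what, " must have 3 coordinate columns", call. = FALSE)
    nm <- rownames(data)
    if (is.null(nm)) nm <- paste0("p", seq_len(nrow(data)))
    coords <- unname(data)
  } else if (is.data.frame(data)) {
    if (ncol(data) < 4L) {
      stop(what, " must have a name column followed by 3 coordinate columns",
           call. = FALSE)
    }
    nm <- as.character(data[[1L]])
    coords <- as.matrix(data[, 2:4])
  } else {
    stop(what, " must be a data frame or a matrix", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop(what, " is empty", call. = FALSE)
  if (!all(is.finite(coords))) stop(what, " has non-finite coordinates", call. = FALSE)
  if (anyDuplicated(nm)) stop(what, " has duplicate entity names", call. = FALSE)
  dimnames(coords) <- NULL
  list(names = nm, coords = coords)
}

.cloud_tibble <- function(names, coords) {
  tibble::tibble(name = names,
                 x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' Convex hull vertices of a 3D point cloud
#'
#' Returns the subset of input points that are vertices of the cloud's 3D
#' convex hull (incremental quickhull). Degenerate inputs -- fewer than five
#' points, or coplanar/collinear clouds -- return all distinct points.
#' Entities sharing a hull-vertex coordinate are all kept.
#'
#' @param data A point cloud: data frame `(name, x, y, z)` or n x 3 matrix.
#' @return A tibble `(name, x, y, z)` of hull vertices, in input order.
#' @export
convex_hull <- function(data) {
  cl <- .as_cloud(data)
  keep <- .hull_vertex_rows(cl$coords)
  .cloud_tibble(cl$names[keep], cl$coords[keep, , drop = FALSE])
}

# row indices (into the full cloud) of convex-hull vertices
.hull_vertex_rows <- function(P) {
  key <- paste(P[, 1], P[, 2], P[, 3], sep = "\r")
  first <- !duplicated(key)
  U <- P[first, , drop = FALSE]
  vid <- .quickhull3_vertices(U)
  hull_keys <- key[first][vid]
  which(key %in% hull_keys)
}

# 3D incremental convex hull on distinct points; returns vertex row indices
# of U. Falls back to all points for degenerate (rank < 3) clouds.
.quickhull3_vertices <- function(U) {
  n <- nrow(U)
  if (n <= 4L) return(seq_len(n))
  scale <- max(apply(U, 2, function(v) diff(range(v))))
  if (scale == 0) return(1L)
  eps <- 1e-9 * scale

  # initial simplex: extreme pair, then farthest from line, then from plane
  i1 <- which.max(U[, 1]); i2 <- which.min(U[, 1])
  if (i1 == i2) { i1 <- which.max(U[, 2]); i2 <- which.min(U[, 2]) }
  if (i1 == i2) { i1 <- which.max(U[, 3]); i2 <- which.min(U[, 3]) }
  d12 <- U[i2, ] - U[i1, ]
  rel <- sweep(U, 2, U[i1, ])
  cross_len2 <- rowSums((rel[, c(2, 3, 1)] * rep(d12[c(3, 1, 2)], each = n) -
                         rel[, c(3, 1, 2)] * rep(d12[c(2, 3, 1)], each = n))^2)
  i3 <- which.max(cross_len2)
  if (sqrt(cross_len2[i3]) <= eps * sqrt(sum(d12^2))) return(seq_len(n)) # collinear
  nrm <- .cross3(d12, U[i3, ] - U[i1, ])
  dist_plane <- as.vector(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(abs(dist_plane))
  if (abs(dist_plane[i4]) <= eps) return(seq_len(n)) # coplanar

  centroid <- colMeans(U[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  fn <- t(apply(faces, 1, function(f) .face_normal(U, f, centroid)))
  off <- rowSums(fn * U[faces[, 1], , drop = FALSE])

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    above <- as.vector(fn %*% U[p, ]) - off > eps
    if (!any(above)) next
    vis <- faces[above, , drop = FALSE]
    # horizon = edges used by exactly one visible face
    edges <- rbind(vis[, c(1, 2)], vis[, c(2, 3)], vis[, c(1, 3)])
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ek %in% names(which(table(ek) == 1L)), , drop = FALSE]
    faces <- faces[!above, , drop = FALSE]
    fn <- fn[!above, , drop = FALSE]
    off <- off[!above]
    for (h in seq_len(nrow(horizon))) {
      f <- c(horizon[h, ], p)
      nrm <- .face_normal(U, f, centroid)
      faces <- rbind(faces, f)
      fn <- rbind(fn, nrm)
      off <- c(off, sum(nrm * U[f[1L], ]))
    }
  }
  sort(unique(as.vector(faces)))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# outward-oriented unit-ish normal of face f (indices into U), relative to an
# interior reference point
.face_normal <- function(U, f, interior) {
  nrm <- .cross3(U[f[2L], ] - U[f[1L], ], U[f[3L], ] - U[f[1L], ])
  if (sum(nrm * (U[f[1L], ] - interior)) < 0) nrm <- -nrm
  nrm
}

#' Similarity-transform parameters
#'
#' The seven fit parameters: translation (CIELAB units), rotation angles
#' (radians, applied intrinsically about the L*, a*, b* axes in that fixed
#' order), and a uniform scale factor.
#'
#' @param translation Numeric length 3.
#' @param angles Numeric length 3 (radians); not normalized to a range.
#' @param scale Positive scalar.
#' @return An object of class `transform_params`.
#' @export
transform_params <- function(translation = c(0, 0, 0),
                             angles = c(0, 0, 0),
                             scale = 1) {
  stopifnot(length(translation) == 3L, length(angles) == 3L, length(scale) == 1L)
  if (!all(is.finite(c(translation, angles, scale)))) {
    stop("transform parameters must be finite", call. = FALSE)
  }
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  structure(list(translation = as.numeric(translation),
                 angles = as.numeric(angles),
                 scale = as.numeric(scale)),
            class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("<transform_params> t = (%.3f, %.3f, %.3f), theta = (%.4f, %.4f, %.4f) rad, s = %.4f\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$angles[1], x$angles[2], x$angles[3], x$scale))
  invisible(x)
}

# R = R_b(theta3) %*% R_a(theta2) %*% R_L(theta1)
.rotation_matrix <- function(theta) {
  c1 <- cos(theta[1]); s1 <- sin(theta[1])
  c2 <- cos(theta[2]); s2 <- sin(theta[2])
  c3 <- cos(theta[3]); s3 <- sin(theta[3])
  RL <- matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, byrow = TRUE)
  Ra <- matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3, byrow = TRUE)
  Rb <- matrix(c(c3, -s3, 0, s3, c3, 0, 0, 0, 1), 3, byrow = TRUE)
  Rb %*% Ra %*% RL
}

#' Apply a similarity transform to a point cloud
#'
#' Maps each point x to `s * R(theta) x + t`. Names and row order are
#' unchanged; all pairwise distances scale exactly by `s`.
#'
#' @param data A point cloud: data frame `(name, x, y, z)` or n x 3 matrix.
#' @param params A [transform_params()].
#' @return A tibble `(name, x, y, z)`.
#' @export
apply_transform <- function(data, params) {
  stopifnot(inherits(params, "transform_params"))
  cl <- .as_cloud(data)
  out <- .apply_transform_matrix(cl$coords, params)
  .cloud_tibble(cl$names, out)
}

.apply_transform_matrix <- function(P, params) {
  R <- .rotation_matrix(params$angles)
  out <- params$scale * (P %*% t(R))
  sweep(out, 2, params$translation, "+")
}
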