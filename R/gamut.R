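# The displayable gamut: the image of the sRGB unit cube in CIELAB.
#
# Membership is analytic -- a Lab point is displayable iff lab_to_srgb() maps
# it into the unit cube -- so no polygon mesh is needed for correctness. A
# triangulated boundary mesh sampled from the cube faces is available for
# visualization. Overshoot (the penalty driver for the fit) is the Euclidean
# Lab distance from a point to the gamut boundary, measured along the ray
# from a fixed interior point and located by bisection.

#' Model of the displayable CIELAB gamut
#'
#' @param interior_point A Lab triple guaranteed to lie inside the gamut;
#'   default the image of mid-gray sRGB (0.5, 0.5, 0.5).
#' @param tolerance Membership tolerance on the sRGB components (dimensionless).
#' @return An object of class `gamut_model`.
#' @export
gamut_model <- function(interior_point = srgb_to_lab(c(0.5, 0.5, 0.5)),
                        tolerance = 1e-9) {
  interior_point <- drop(.as_color_matrix(interior_point, "interior_point"))
  stopifnot(tolerance > 0)
  g <- structure(
    list(interior_point = interior_point, tolerance = tolerance),
    class = "gamut_model"
  )
  if (!in_gamut(rbind(interior_point), g)) {
    stop("interior_point is not inside the displayable gamut", call. = FALSE)
  }
  g
}

#' @export
print.gamut_model <- function(x, ...) {
  cat("<gamut_model> displayable sRGB region of CIELAB (D65)\n")
  cat(sprintf("  interior point: L=%.2f a=%.2f b=%.2f; tolerance %g\n",
              x$interior_point[1], x$interior_point[2], x$interior_point[3],
              x$tolerance))
  invisible(x)
}

#' Test whether CIELAB colors are displayable
#'
#' A Lab point is in gamut iff its sRGB image has all components in
#' `[-tol, 1 + tol]`. The gamut is exactly the preimage of the unit RGB cube,
#' so the test is analytic and has no mesh-resolution artifacts.
#'
#' @param lab A length-3 vector or n x 3 matrix of CIELAB coordinates.
#' @param gamut A [gamut_model()].
#' @return A logical vector of length n.
#' @export
in_gamut <- function(lab, gamut = gamut_model()) {
  rgb <- lab_to_srgb(lab)
  tol <- gamut$tolerance
  rowSums(rgb < -tol | rgb > 1 + tol) == 0
}

.in_gamut_raw <- function(lab, tol) {
  rgb <- .lab2rgb_raw(lab)
  rgb[, 1] >= -tol & rgb[, 1] <= 1 + tol &
    rgb[, 2] >= -tol & rgb[, 2] <= 1 + tol &
    rgb[, 3] >= -tol & rgb[, 3] <= 1 + tol
}

# validation-free overshoot kernel shared by gamut_overshoot() and the fit
.overshoot_raw <- function(lab, interior, tol, steps) {
  res <- numeric(nrow(lab))
  outside <- !.in_gamut_raw(lab, tol)
  if (!any(outside)) return(res)
  p <- lab[outside, , drop = FALSE]
  anchor <- matrix(interior, nrow(p), 3, byrow = TRUE)
  dir <- p - anchor
  lo <- numeric(nrow(p)) # in gamut at t = 0 (interior point)
  hi <- rep(1, nrow(p))  # out of gamut at t = 1 (the point itself)
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    inside <- .in_gamut_raw(anchor + mid * dir, tol)
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  res[outside] <- (1 - (lo + hi) / 2) * sqrt(rowSums(dir^2))
  res
}

#' Distance by which CIELAB colors protrude outside the gamut
#'
#' For an out-of-gamut point p, the boundary crossing on the segment from the
#' gamut's interior point to p is located by bisection (48 steps) and the
#' overshoot is the Euclidean Lab distance from p to that crossing. In-gamut
#' points return 0. The result is deterministic.
#'
#' @inheritParams in_gamut
#' @param steps Number of bisection steps (each halves the bracket).
#' @return A numeric vector of nonnegative distances in CIELAB units.
#' @export
gamut_overshoot <- function(lab, gamut = gamut_model(), steps = 48L) {
  lab <- .as_color_matrix(lab, "lab")
  .overshoot_raw(lab, gamut$interior_point, gamut$tolerance, steps)
}

#' Triangulated boundary mesh of the gamut (visualization only)
#'
#' Samples each face of the sRGB cube on a k x k grid and maps it to CIELAB.
#'
#' @param k Grid resolution per cube face.
#' @return A list with `vertices` (m x 3 Lab matrix) and `faces`
#'   (t x 3 integer matrix of 1-based vertex indices).
#' @export
gamut_mesh <- function(k = 12L) {
  stopifnot(k >= 2L)
  u <- seq(0, 1, length.out = k)
  grid <- expand.grid(u = u, v = u)
  verts <- list(); faces <- list(); offset <- 0L
  # index helper for the k x k grid laid out u-fastest
  idx <- function(i, j) (j - 1L) * k + i
  quads <- do.call(rbind, lapply(seq_len(k - 1L), function(j) {
    i <- seq_len(k - 1L)
    cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }))
  tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  for (axis in 1:3) {
    for (level in c(0, 1)) {
      face_rgb <- matrix(level, nrow(grid), 3)
      face_rgb[, setdiff(1:3, axis)] <- as.matrix(grid)
      verts[[length(verts) + 1L]] <- srgb_to_lab(face_rgb)
      faces[[length(faces) + 1L]] <- tris + offset
      offset <- offset + nrow(grid)
    }
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

#' Write a gamut mesh as a Wavefront OBJ file
#'
#' @param mesh A mesh as returned by [gamut_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  v <- sprintf("v %.6f %.6f %.6f",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

#' Distance from the interior point to the gamut boundary along rays
#'
#' For each direction, the boundary crossing of the ray from the gamut's
#' interior point is bracketed by doubling and then located by bisection.
#' The minimum over many directions estimates the radius of the largest ball
#' centered at the interior point that fits inside the gamut.
#'
#' @param directions An n x 3 matrix of ray directions (need not be unit).
#' @param gamut A [gamut_model()].
#' @param steps Number of bisection steps.
#' @return A numeric vector of distances in CIELAB units.
#' @export
gamut_ray_radius <- function(directions, gamut = gamut_model(), steps = 48L) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  directions <- directions / sqrt(rowSums(directions^2))
  anchor <- matrix(gamut$interior_point, nrow(directions), 3, byrow = TRUE)
  hi <- rep(1, nrow(directions))
  for (i in 1:12) { # the gamut fits inside a radius-4096 ball many times over
    outside <- !in_gamut(anchor + hi * directions, gamut)
    if (all(outside)) break
    hi[!outside] <- 2 * hi[!outside]
  }
  lo <- numeric(nrow(directions))
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    inside <- in_gamut(anchor + mid * directions, gamut)
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  (lo + hi) / 2
}
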