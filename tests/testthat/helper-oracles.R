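# Independent oracles and shared fixtures for the test suite.

# Quadratic-programming point-in-hull test (quadprog): the squared distance
# from p to the convex hull of the rows of X. Independent of the package's
# own quickhull implementation.
qp_hull_distance <- function(p, X) {
  n <- nrow(X)
  D <- crossprod(t(X)) + diag(1e-10, n)
  d <- as.numeric(X %*% p)
  A <- cbind(rep(1, n), diag(n))
  sol <- quadprog::solve.QP(D, d, A, c(1, rep(0, n)), meq = 1)
  proj <- as.numeric(t(X) %*% sol$solution)
  sum((proj - p)^2)
}

# p is a vertex of the hull of rbind(X, p) iff it is NOT in the hull of X
qp_is_vertex <- function(i, P, tol = 1e-6) {
  qp_hull_distance(P[i, ], P[-i, , drop = FALSE]) > tol
}

# reference color conversion (farver), for oracle equivalence checks
ref_srgb_to_lab <- function(rgb01) {
  farver::convert_colour(rgb01 * 255, from = "rgb", to = "lab")
}

pairwise_dist <- function(m) as.numeric(stats::dist(m))

mean_within_between <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  ut <- upper.tri(d)
  c(within = mean(d[ut & same & !is.na(same)]),
    between = mean(d[ut & !same]))
}

# the reference study cloud: seeded 500-point standard Gaussian in 3D
gaussian_cloud <- function(n = 500L, seed = 7L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(3 * n), ncol = 3)
  })
  rownames(m) <- sprintf("g%03d", seq_len(n))
  m
}

# Full-condition 25-start fits are expensive; cache them across test files.
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, data, ...) {
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- fit_colors(data, ...)
  }
  .fit_cache[[key]]
}
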