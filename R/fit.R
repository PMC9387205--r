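# The core fit: place a 3D point cloud inside the displayable CIELAB gamut.
#
# The cloud is normalized (centroid to the origin, max radius to 1), reduced
# to its convex-hull vertices, and a 7-parameter similarity transform
# (translation, Euler rotation about the L*/a*/b* axes, uniform scale) is
# optimized with multi-start Nelder-Mead. The objective rewards spread --
# the weighted mean of the per-axis extents of the transformed hull -- and
# penalizes protrusion by lambda times the SUM of hull-vertex overshoots.
# The sum makes the marginal cost of pushing any single vertex out equal to
# lambda (independent of how many vertices the hull has), whereas the
# marginal size gain per unit of protrusion is bounded by
# max_u sum_k w_k |u_k| / sum(w) <= sqrt(3)/3; lambda = 10 therefore keeps
# every hull vertex essentially inside at the optimum. A mean-based penalty
# would dilute the cost by the vertex count and let isolated vertices
# protrude arbitrarily far on hulls with more than ~17 vertices.

#' Fit configuration
#'
#' @param n_starts Number of Nelder-Mead starts; the first uses the identity
#'   rotation, the rest use rotation angles drawn uniformly from `[0, 2*pi)`.
#' @param penalty_lambda Weight of the out-of-gamut penalty.
#' @param seed Integer seed for the initial rotations.
#' @param max_iter Maximum simplex iterations per start.
#' @param tol Absolute convergence tolerance on parameters and objective.
#' @param init_scale Initial uniform scale (CIELAB units per unit cloud
#'   radius); 40 starts the unit-radius cloud comfortably inside the gamut.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 25L, penalty_lambda = 10, seed = 42L,
                       max_iter = 2000L, tol = 1e-6, init_scale = 40) {
  stopifnot(n_starts >= 1L, penalty_lambda > 0, max_iter >= 1L, tol > 0,
            init_scale > 0)
  structure(list(n_starts = as.integer(n_starts),
                 penalty_lambda = penalty_lambda,
                 seed = as.integer(seed),
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 init_scale = init_scale),
            class = "fit_config")
}

.check_weights <- function(weights) {
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be 3 nonnegative finite values, not all zero",
         call. = FALSE)
  }
  as.numeric(weights)
}

#' Fit objective: weighted spread minus out-of-gamut penalty
#'
#' Evaluates `size - lambda * total_overshoot` for a transformed hull, where
#' size is the weighted mean of the transformed hull's extents along the L*,
#' a*, and b* axes and total_overshoot sums [gamut_overshoot()] over the
#' hull vertices; summing (not averaging) keeps the marginal cost of any one
#' protruding vertex at `lambda` regardless of hull size.
#'
#' @param hull A point cloud of convex-hull vertices (data frame or matrix),
#'   already normalized to centroid 0 and max radius 1.
#' @param params A [transform_params()].
#' @param weights Nonnegative axis weights `(L, a, b)`.
#' @param penalty_lambda Penalty weight.
#' @param gamut A [gamut_model()].
#' @return The scalar objective value (to be maximized).
#' @export
fit_objective <- function(hull, params, weights = c(1, 1, 1),
                          penalty_lambda = 10, gamut = gamut_model()) {
  stopifnot(inherits(params, "transform_params"))
  weights <- .check_weights(weights)
  cl <- .as_cloud(hull, "hull")
  .objective_matrix(cl$coords,
                    c(params$translation, params$angles, params$scale),
                    weights, penalty_lambda, gamut)
}

# par = c(t1, t2, t3, theta1, theta2, theta3, s); H is the hull matrix
.objective_matrix <- function(H, par, weights, lambda, gamut) {
  s <- par[7]
  if (!all(is.finite(par))) return(-1e6)
  if (s <= 1e-8) return(-1e3 * (2 + abs(s))) # steer the simplex back to s > 0
  R <- .rotation_matrix(par[4:6])
  T <- s * (H %*% t(R))
  T[, 1] <- T[, 1] + par[1]; T[, 2] <- T[, 2] + par[2]; T[, 3] <- T[, 3] + par[3]
  ext <- c(max(T[, 1]) - min(T[, 1]), max(T[, 2]) - min(T[, 2]),
           max(T[, 3]) - min(T[, 3]))
  size <- sum(weights * ext) / sum(weights)
  size - lambda * sum(.overshoot_raw(T, gamut$interior_point,
                                     gamut$tolerance, 48L))
}

#' Fit a 3D point cloud inside the displayable CIELAB gamut
#'
#' The core optimization: normalizes the cloud (centroid to the origin,
#' maximum point norm to 1), extracts its convex hull, and runs multi-start
#' Nelder-Mead over the seven similarity-transform parameters to make the
#' hull as large as possible inside the gamut (see [fit_objective()]).
#' Deterministic given `config$seed`; ties across starts break toward the
#' lowest start index.
#'
#' @param data A point cloud: data frame `(name, x, y, z)` or n x 3 matrix.
#' @param weights Nonnegative axis weights `(L, a, b)`; larger weight
#'   prioritizes spreading the cloud along that CIELAB axis.
#' @param config A [fit_config()].
#' @param gamut A [gamut_model()].
#' @return An object of class `colorcloud_fit`: best [transform_params()],
#'   objective, the normalization (centroid, radius), and the ranked table
#'   of all starts' solutions.
#' @examples
#' pts <- matrix(rnorm(150), ncol = 3)
#' fit <- fit_colors(pts, config = fit_config(n_starts = 3L))
#' glance(fit)
#' @export
fit_colors <- function(data, weights = c(1, 1, 1), config = fit_config(),
                       gamut = gamut_model()) {
  weights <- .check_weights(weights)
  stopifnot(inherits(config, "fit_config"), inherits(gamut, "gamut_model"))
  cl <- .as_cloud(data)

  centroid <- colMeans(cl$coords)
  centered <- sweep(cl$coords, 2, centroid)
  radius <- sqrt(max(rowSums(centered^2)))
  if (radius == 0) radius <- 1 # single point / all-identical cloud
  normed <- centered / radius
  H <- normed[.hull_vertex_rows(normed), , drop = FALSE]

  # initial rotations: identity first, then seeded uniform draws on [0, 2*pi)
  n_rand <- config$n_starts - 1L
  rand_angles <- if (n_rand > 0L) {
    old <- .save_seed()
    set.seed(config$seed)
    m <- matrix(stats::runif(3L * n_rand, 0, 2 * pi), ncol = 3L, byrow = TRUE)
    .restore_seed(old)
    m
  } else {
    matrix(numeric(0), ncol = 3L)
  }
  init_angles <- rbind(c(0, 0, 0), rand_angles)

  lambda <- config$penalty_lambda
  runs <- lapply(seq_len(config$n_starts), function(i) {
    par0 <- c(gamut$interior_point, init_angles[i, ], config$init_scale)
    opt <- stats::optim(
      par0,
      fn = function(p) .objective_matrix(H, p, weights, lambda, gamut),
      method = "Nelder-Mead",
      control = list(fnscale = -1, maxit = config$max_iter,
                     reltol = config$tol * 1e-2)
    )
    list(par = opt$par, objective = opt$value, convergence = opt$convergence)
  })

  alt <- tibble::tibble(
    start = seq_len(config$n_starts),
    objective = purrr::map_dbl(runs, "objective"),
    t_L = purrr::map_dbl(runs, ~ .x$par[1]),
    t_a = purrr::map_dbl(runs, ~ .x$par[2]),
    t_b = purrr::map_dbl(runs, ~ .x$par[3]),
    theta_L = purrr::map_dbl(runs, ~ .x$par[4]),
    theta_a = purrr::map_dbl(runs, ~ .x$par[5]),
    theta_b = purrr::map_dbl(runs, ~ .x$par[6]),
    scale = purrr::map_dbl(runs, ~ .x$par[7]),
    converged = purrr::map_int(runs, "convergence") == 0L
  )
  alt <- dplyr::arrange(alt, dplyr::desc(.data$objective), .data$start)

  best_par <- runs[[alt$start[1]]]$par
  best <- transform_params(translation = best_par[1:3],
                           angles = best_par[4:6],
                           scale = best_par[7])
  structure(
    list(
      best = best,
      objective = alt$objective[1],
      normalization = list(centroid = centroid, radius = radius),
      alternatives = alt,
      weights = weights,
      config = config,
      gamut = gamut,
      n_points = nrow(cl$coords),
      n_hull = nrow(H)
    ),
    class = "colorcloud_fit"
  )
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.colorcloud_fit <- function(x, ...) {
  cat("<colorcloud_fit>\n")
  cat(sprintf("  %d points (%d hull vertices), %d starts, objective %.4f\n",
              x$n_points, x$n_hull, x$config$n_starts, x$objective))
  cat(sprintf("  best scale %.2f CIELAB units per unit cloud radius\n",
              x$best$scale))
  print(x$best)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Ranked multi-start solutions of a color fit
#'
#' @param x A `colorcloud_fit`.
#' @param ... Unused.
#' @return A tibble with one row per start, best first.
#' @method tidy colorcloud_fit
#' @export
tidy.colorcloud_fit <- function(x, ...) x$alternatives

#' One-row summary of a color fit
#'
#' @param x A `colorcloud_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance colorcloud_fit
#' @export
glance.colorcloud_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    scale = x$best$scale,
    n_points = x$n_points,
    n_hull = x$n_hull,
    n_starts = x$config$n_starts,
    penalty_lambda = x$config$penalty_lambda,
    cloud_radius = x$normalization$radius
  )
}

#' Assign CIELAB colors to points using a fitted transform
#'
#' Applies the fit's normalization and best transform to the points --
#' either the fitted cloud or new points in the same coordinate frame -- and
#' converts the result to CIELAB coordinates and/or sRGB hex codes. Points
#' that land outside the gamut (possible for non-hull points, since the
#' gamut is not convex, and for new data) are clamped channel-wise in sRGB
#' when `clamp = TRUE`, with a warning giving the count.
#'
#' @param data A point cloud: data frame `(name, x, y, z)` or n x 3 matrix,
#'   in the same coordinate frame as the cloud passed to [fit_colors()].
#' @param fit A `colorcloud_fit`.
#' @param format `"both"` (default), `"hex"`, or `"lab"`: which color
#'   columns to return.
#' @param clamp If `FALSE`, out-of-gamut points raise an error listing the
#'   offending names instead of being clamped.
#' @return A tibble in input row order with column `name` plus, by format,
#'   `L`, `a`, `b` and/or `hex`.
#' @export
encode_colors <- function(data, fit, format = c("both", "hex", "lab"),
                          clamp = TRUE) {
  stopifnot(inherits(fit, "colorcloud_fit"))
  format <- match.arg(format)
  cl <- .as_cloud(data)
  normed <- sweep(cl$coords, 2, fit$normalization$centroid) /
    fit$normalization$radius
  lab <- .apply_transform_matrix(normed, fit$best)
  colnames(lab) <- c("L", "a", "b")

  outside <- !in_gamut(lab, fit$gamut)
  if (any(outside)) {
    if (!clamp) {
      stop("points outside the displayable gamut with clamp = FALSE: ",
           paste(utils::head(cl$names[outside], 10L), collapse = ", "),
           if (sum(outside) > 10L) sprintf(" (and %d more)", sum(outside) - 10L),
           call. = FALSE)
    }
    warning(sprintf("%d of %d points fell outside the displayable gamut and were clamped in sRGB",
                    sum(outside), nrow(lab)), call. = FALSE)
  }

  out <- tibble::tibble(name = cl$names)
  if (format %in% c("both", "lab")) {
    out$L <- lab[, 1]; out$a <- lab[, 2]; out$b <- lab[, 3]
  }
  if (format %in% c("both", "hex")) out$hex <- lab_to_hex(lab, clamp = TRUE)
  attr(out, "n_clamped") <- sum(outside)
  class(out) <- c("colorcloud_table", class(out))
  out
}

#' Fit and encode in one step
#'
#' Convenience wrapper running [fit_colors()] then [encode_colors()] on the
#' same cloud. The fit is attached as the `"fit"` attribute of the returned
#' color table.
#'
#' @inheritParams fit_colors
#' @inheritParams encode_colors
#' @return A color-table tibble (see [encode_colors()]) with the
#'   `colorcloud_fit` in `attr(, "fit")`.
#' @export
cloud_colors <- function(data, weights = c(1, 1, 1), config = fit_config(),
                         gamut = gamut_model(),
                         format = c("both", "hex", "lab"), clamp = TRUE) {
  fit <- fit_colors(data, weights = weights, config = config, gamut = gamut)
  out <- encode_colors(data, fit, format = format, clamp = clamp)
  attr(out, "fit") <- fit
  out
}

#' Save a color fit as JSON
#'
#' Serializes the best transform, normalization, objective, and the full
#' table of alternative solutions so a fit can be reapplied to new data in
#' another session with [read_color_fit()].
#'
#' @param fit A `colorcloud_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_color_fit <- function(fit, path) {
  stopifnot(inherits(fit, "colorcloud_fit"))
  obj <- list(
    best = list(translation = fit$best$translation,
                angles = fit$best$angles,
                scale = fit$best$scale),
    objective = fit$objective,
    normalization = fit$normalization,
    weights = fit$weights,
    config = unclass(fit$config),
    gamut = list(interior_point = fit$gamut$interior_point,
                 tolerance = fit$gamut$tolerance),
    n_points = fit$n_points,
    n_hull = fit$n_hull,
    alternatives = fit$alternatives
  )
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a color fit saved by [write_color_fit()]
#'
#' @param path Path to the JSON file.
#' @return A `colorcloud_fit`.
#' @export
read_color_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  structure(
    list(
      best = transform_params(obj$best$translation, obj$best$angles,
                              obj$best$scale),
      objective = obj$objective,
      normalization = list(centroid = obj$normalization$centroid,
                           radius = obj$normalization$radius),
      alternatives = tibble::as_tibble(obj$alternatives),
      weights = obj$weights,
      config = fit_config(cfg$n_starts, cfg$penalty_lambda, cfg$seed,
                          cfg$max_iter, cfg$tol, cfg$init_scale),
      gamut = gamut_model(obj$gamut$interior_point, obj$gamut$tolerance),
      n_points = obj$n_points,
      n_hull = obj$n_hull
    ),
    class = "colorcloud_fit"
  )
}
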