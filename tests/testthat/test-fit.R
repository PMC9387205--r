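g <- gamut_model()

test_that("the objective decomposes into weighted spread minus penalty", {
  # a single point placed at the interior point has no spread and no penalty
  pt <- matrix(0, 1, 3, dimnames = list("a", NULL))
  prm <- transform_params(translation = g$interior_point, scale = 10)
  expect_equal(fit_objective(pt, prm, gamut = g), 0)

  # two points spanning the L* axis by 20 units, all in gamut
  seg <- matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("lo", "hi"), NULL))
  expect_equal(fit_objective(seg, prm, weights = c(1, 1, 1), gamut = g),
               20 / 3, tolerance = 1e-9)

  # unequal weights follow the weighted-mean definition
  expect_equal(fit_objective(seg, prm, weights = c(2, 1, 1), gamut = g),
               2 * 20 / 4, tolerance = 1e-9)

  # a tetrahedron pushed partly outside: objective equals the independently
  # assembled size - lambda * sum(overshoot)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rownames(tet) <- paste0("t", 1:4)
  prm2 <- transform_params(translation = c(53, 80, 0), angles = c(0.2, 0.1, -0.3),
                           scale = 60)
  moved <- as.matrix(apply_transform(tet, prm2)[, 2:4])
  ext <- apply(moved, 2, function(v) diff(range(v)))
  expected <- mean(ext) - 10 * sum(gamut_overshoot(moved, g))
  expect_gt(max(gamut_overshoot(moved, g)), 0) # at least one vertex protrudes
  expect_equal(fit_objective(tet, prm2, penalty_lambda = 10, gamut = g),
               expected, tolerance = 1e-9)
})

test_that("a single-point cloud fits with zero objective and zero overshoot", {
  one <- matrix(c(4, -2, 9), 1, dimnames = list("only", NULL))
  fit <- fit_colors(one, config = fit_config(n_starts = 2L, max_iter = 200L))
  expect_equal(fit$objective, 0, tolerance = 1e-6)
  tab <- encode_colors(one, fit)
  expect_equal(gamut_overshoot(as.matrix(tab[, c("L", "a", "b")]), g), 0)
})

test_that("the best solution dominates all starts and ties are deterministic", {
  withr::with_seed(41, {
    X <- matrix(rnorm(120), ncol = 3)
  })
  rownames(X) <- paste0("p", 1:40)
  fit <- fit_colors(X, config = fit_config(n_starts = 4L, seed = 5L))
  alt <- tidy(fit)
  expect_equal(nrow(alt), 4)
  expect_true(all(fit$objective >= alt$objective))
  expect_equal(alt$objective[1], fit$objective)
  expect_equal(alt$scale[1], fit$best$scale)
  # rerun: identical result given the same seed
  fit2 <- fit_colors(X, config = fit_config(n_starts = 4L, seed = 5L))
  expect_identical(tidy(fit), tidy(fit2))
  expect_identical(fit$best, fit2$best)
})

test_that("a larger out-of-gamut penalty never increases the fitted scale", {
  withr::with_seed(43, {
    X <- matrix(rnorm(90), ncol = 3)
  })
  rownames(X) <- paste0("p", 1:30)
  scales <- vapply(c(1, 10, 100), function(lam) {
    fit_colors(X, config = fit_config(n_starts = 10L, penalty_lambda = lam,
                                      seed = 2L))$best$scale
  }, numeric(1))
  # non-increasing up to multi-start optimizer variation (~2%)
  expect_true(all(diff(scales) <= 0.02 * scales[-length(scales)]))
})

test_that("axis weights steer spread toward the weighted axis", {
  withr::with_seed(47, {
    X <- cbind(rnorm(40, sd = 3), rnorm(40), rnorm(40))
  })
  rownames(X) <- paste0("p", 1:40)
  ext_L <- function(w) {
    tab <- cloud_colors(X, weights = w, config = fit_config(n_starts = 5L))
    diff(range(tab$L))
  }
  expect_gt(suppressWarnings(ext_L(c(10, 1, 1))),
            suppressWarnings(ext_L(c(1, 1, 10))))
})

test_that("encoding preserves identity, order, and pairwise distance ratios", {
  withr::with_seed(53, {
    X <- matrix(rnorm(150), ncol = 3)
  })
  X <- rbind(X, X[1, , drop = FALSE]) # a duplicated coordinate
  rownames(X) <- c(paste0("p", 1:50), "p1copy")
  fit <- cached_fit("small", X, config = fit_config(n_starts = 5L, seed = 3L))
  tab <- suppressWarnings(encode_colors(X, fit, format = "both"))
  expect_identical(tab$name, rownames(X))
  expect_identical(tab$hex[1], tab$hex[51])
  expect_true(all(grepl("^#[0-9A-F]{6}$", tab$hex)))
  # pre-clamp Lab distances are an exact multiple of input distances
  ratio <- fit$best$scale / fit$normalization$radius
  expect_equal(pairwise_dist(as.matrix(tab[, c("L", "a", "b")])),
               ratio * pairwise_dist(X), tolerance = 1e-9)
  expect_equal(stats::cor(pairwise_dist(as.matrix(tab[, c("L", "a", "b")])),
                          pairwise_dist(X)), 1, tolerance = 1e-9)
})

test_that("clamp = FALSE names the offending out-of-gamut points", {
  withr::with_seed(53, {
    X <- matrix(rnorm(150), ncol = 3)
  })
  rownames(X) <- paste0("p", 1:50)
  fit <- cached_fit("small50", X, config = fit_config(n_starts = 5L, seed = 3L))
  far <- matrix(c(100, 100, 100), 1, dimnames = list("runaway", NULL))
  expect_error(encode_colors(far, fit, clamp = FALSE), "runaway")
  tab <- suppressWarnings(encode_colors(far, fit, clamp = TRUE))
  expect_equal(attr(tab, "n_clamped"), 1L)
})

test_that("a saved fit reapplies identically from JSON", {
  withr::with_seed(59, {
    X <- matrix(rnorm(60), ncol = 3)
  })
  rownames(X) <- paste0("p", 1:20)
  fit <- fit_colors(X, config = fit_config(n_starts = 2L, seed = 9L))
  path <- withr::local_tempfile(fileext = ".json")
  write_color_fit(fit, path)
  fit2 <- read_color_fit(path)
  expect_equal(fit2$best$translation, fit$best$translation)
  expect_equal(fit2$best$scale, fit$best$scale)
  expect_equal(fit2$objective, fit$objective)
  t1 <- suppressWarnings(encode_colors(X, fit))
  t2 <- suppressWarnings(encode_colors(X, fit2))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  # new points in the same frame reuse the stored normalization
  new_pts <- matrix(c(0.1, 0.2, -0.1), 1, dimnames = list("new", NULL))
  expect_equal(as.data.frame(suppressWarnings(encode_colors(new_pts, fit2))),
               as.data.frame(suppressWarnings(encode_colors(new_pts, fit))))
})

test_that("fit summaries expose the key quantities", {
  withr::with_seed(61, {
    X <- matrix(rnorm(60), ncol = 3)
  })
  rownames(X) <- paste0("p", 1:20)
  fit <- fit_colors(X, config = fit_config(n_starts = 2L))
  gl <- glance(fit)
  expect_equal(gl$n_points, 20)
  expect_equal(gl$n_starts, 2)
  expect_equal(gl$objective, fit$objective)
  expect_output(print(fit), "colorcloud_fit")
})
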