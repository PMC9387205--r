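test_that("log-normalization follows the per-cell formula", {
  counts <- matrix(c(0, 1, 9999, 0, 5, 5), nrow = 3)
  rownames(counts) <- paste0("g", 1:3); colnames(counts) <- c("c1", "c2")
  norm <- lognormalize_counts(counts, scale_factor = 1e4)
  expect_equal(norm["g1", "c1"], 0)             # zero stays zero
  expect_equal(norm["g2", "c1"], log(2))        # count 1, total 1e4 -> log 2
  expect_equal(norm["g2", "c2"], log(1 + 5 * 1e4 / 10))
  norm2 <- lognormalize_counts(counts, log_base = 2)
  expect_equal(norm2["g2", "c1"], log2(2))
  expect_error(lognormalize_counts(cbind(counts, c3 = c(0, 0, 0))), "zero total")
})

test_that("the high-dimensional track separates known clusters in 3D", {
  s <- synth_highdim_clusters(n = 300L, dim = 50L, seed = 101L)
  cloud <- reduce_highdim(s$data, seed = 7L)
  expect_identical(cloud$name, s$data$name)
  expect_true(all(is.finite(as.matrix(cloud[, 2:4]))))
  wb <- mean_within_between(as.matrix(cloud[, 2:4]), s$labels)
  expect_lt(wb["within"], wb["between"])
  # determinism: same input and seed give identical coordinates
  cloud2 <- reduce_highdim(s$data, seed = 7L)
  expect_identical(cloud, cloud2)
})

test_that("a 3-column matrix passes through the PCA + UMAP shape contract", {
  withr::with_seed(67, {
    m <- matrix(rnorm(60), ncol = 3)
  })
  rownames(m) <- paste0("p", 1:20)
  cloud <- reduce_highdim(m, n_pcs = 3L, n_neighbors = 5L, seed = 1L)
  expect_equal(dim(cloud), c(20L, 4L))
  expect_identical(cloud$name, rownames(m))
})

test_that("degenerate and undersized inputs fail with clear errors", {
  const <- matrix(1, 10, 5, dimnames = list(paste0("p", 1:10), NULL))
  expect_error(reduce_highdim(const), "variance")
  tiny <- matrix(rnorm(12), 4, dimnames = list(paste0("p", 1:4), NULL))
  expect_error(reduce_highdim(tiny), "too few entities")
  expect_error(reduce_distance(matrix(0, 3, 3,
    dimnames = list(paste0("e", 1:3), paste0("e", 1:3)))), "too few entities")
})

test_that("the single-cell track groups module-mate genes", {
  s <- synth_sc_counts(n_genes = 90L, n_cells = 60L, seed = 103L)
  expect_error(reduce_single_cell(-1 * as.matrix(s$counts)), "nonnegative")
  cloud <- reduce_single_cell(s$counts, seed = 7L)
  expect_identical(cloud$name, rownames(s$counts))
  wb <- mean_within_between(as.matrix(cloud[, 2:4]), s$labels)
  expect_lt(wb["within"], wb["between"])
  expect_identical(cloud, reduce_single_cell(s$counts, seed = 7L))
})

test_that("zero-total cells are dropped with a warning", {
  s <- synth_sc_counts(n_genes = 30L, n_cells = 20L, seed = 105L)
  counts <- as.matrix(s$counts)
  counts[, 3] <- 0
  expect_warning(
    cloud <- reduce_single_cell(counts, n_neighbors = 10L, seed = 1L),
    "zero total"
  )
  expect_equal(nrow(cloud), 30L)
})

test_that("the distance-matrix track embeds cliques coherently", {
  s <- synth_cliques_dist(n = 60L, seed = 107L)
  cloud <- reduce_distance(s$dist, seed = 7L)
  expect_identical(cloud$name, rownames(s$dist))
  wb <- mean_within_between(as.matrix(cloud[, 2:4]), s$labels)
  expect_lt(wb["within"], wb["between"])
})

test_that("distance-matrix validation catches malformed input", {
  d <- synth_cliques_dist(n = 20L, seed = 109L)$dist
  asym <- d; asym[1, 2] <- asym[1, 2] + 1
  expect_error(reduce_distance(asym), "symmetric")
  expect_silent(reduce_distance(asym, symmetrize = TRUE, n_neighbors = 5L))
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(reduce_distance(neg), "nonnegative")
  offdiag <- d; diag(offdiag) <- 0.5
  expect_error(reduce_distance(offdiag), "diagonal")
  expect_error(reduce_distance(d[, 1:10]), "square")
  # all-equal off-diagonal distances still embed (shape contract only)
  eq <- matrix(1, 20, 20, dimnames = dimnames(d)); diag(eq) <- 0
  cloud <- reduce_distance(eq, n_neighbors = 5L, seed = 1L)
  expect_equal(dim(cloud), c(20L, 4L))
})
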