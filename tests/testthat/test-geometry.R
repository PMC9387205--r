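test_that("convex hull keeps exactly the extreme points", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  cloud <- rbind(cube, c(0.5, 0.5, 0.5))
  rownames(cloud) <- paste0("v", 1:9)
  h <- convex_hull(cloud)
  expect_setequal(h$name, paste0("v", 1:8))

  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rownames(tetra) <- paste0("t", 1:4)
  expect_setequal(convex_hull(tetra)$name, paste0("t", 1:4))
})

test_that("axis spikes at radius 2 dominate a unit ball's hull", {
  withr::with_seed(23, {
    dirs <- matrix(rnorm(600), ncol = 3)
    ball <- dirs / sqrt(rowSums(dirs^2)) * runif(200)^(1 / 3)
  })
  spikes <- rbind(diag(2, 3), -diag(2, 3))
  P <- rbind(ball, spikes)
  rownames(P) <- c(sprintf("b%03d", 1:200), sprintf("s%d", 1:6))
  h <- convex_hull(P)
  expect_true(all(sprintf("s%d", 1:6) %in% h$name))
})

test_that("hull vertices agree with the quadratic-programming oracle", {
  withr::with_seed(29, {
    P <- matrix(rnorm(150), ncol = 3)
  })
  rownames(P) <- sprintf("p%02d", 1:50)
  hull_names <- convex_hull(P)$name
  oracle <- vapply(seq_len(nrow(P)), qp_is_vertex, logical(1), P = P)
  expect_setequal(hull_names, rownames(P)[oracle])
})

test_that("degenerate clouds return all distinct points", {
  flat <- cbind(matrix(runif(20, -1, 1), ncol = 2), 0)
  rownames(flat) <- paste0("f", 1:10)
  expect_equal(nrow(convex_hull(flat)), 10)
  line <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  rownames(line) <- paste0("l", 1:6)
  expect_equal(nrow(convex_hull(line)), 6)
  one <- matrix(c(1, 2, 3), 1, dimnames = list("a", NULL))
  expect_equal(nrow(convex_hull(one)), 1)
  # duplicate coordinates: both entities kept
  dup <- rbind(diag(3), diag(3)[1, , drop = FALSE], c(0, 0, 0))
  rownames(dup) <- paste0("d", 1:5)
  h <- convex_hull(dup)
  expect_true(all(c("d1", "d4") %in% h$name))
})

test_that("non-vertices stay inside the transformed hull (hull sufficiency)", {
  withr::with_seed(31, {
    P <- matrix(rnorm(240), ncol = 3)
    params <- transform_params(translation = runif(3, -5, 5),
                               angles = runif(3, 0, 2 * pi), scale = 3.7)
  })
  rownames(P) <- sprintf("p%02d", seq_len(nrow(P)))
  hull_names <- convex_hull(P)$name
  TP <- apply_transform(P, params)
  tm <- as.matrix(TP[, c("x", "y", "z")])
  hull_rows <- tm[TP$name %in% hull_names, , drop = FALSE]
  inner_rows <- tm[!TP$name %in% hull_names, , drop = FALSE]
  d2 <- vapply(seq_len(nrow(inner_rows)),
               function(i) qp_hull_distance(inner_rows[i, ], hull_rows),
               numeric(1))
  expect_lt(max(d2), 1e-8)
})

test_that("apply_transform is an exact similarity", {
  withr::with_seed(37, {
    P <- matrix(rnorm(90), ncol = 3)
  })
  rownames(P) <- paste0("p", 1:30)
  id <- transform_params()
  expect_equal(unname(as.matrix(apply_transform(P, id)[, 2:4])), unname(P))

  p2 <- transform_params(scale = 2)
  expect_equal(unname(as.matrix(apply_transform(matrix(c(1, 0, 0), 1), p2)[, 2:4])),
               matrix(c(2, 0, 0), 1))

  prm <- transform_params(translation = c(3, -1, 2),
                          angles = c(0.3, -1.2, 2.5), scale = 1.9)
  out <- as.matrix(apply_transform(P, prm)[, 2:4])
  expect_equal(pairwise_dist(out), 1.9 * pairwise_dist(P), tolerance = 1e-12)
  expect_equal(stats::cor(pairwise_dist(out), pairwise_dist(P)), 1,
               tolerance = 1e-12)
  # rotation part is a proper rotation
  R <- colorcloud:::.rotation_matrix(c(0.3, -1.2, 2.5))
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("invalid transforms and clouds are rejected", {
  expect_error(transform_params(scale = 0), "scale")
  expect_error(transform_params(scale = -1), "scale")
  expect_error(transform_params(angles = c(Inf, 0, 0)), "finite")
  bad <- matrix(c(1, NA, 3), 1)
  expect_error(convex_hull(bad), "non-finite")
  dupnames <- matrix(rnorm(6), 2, dimnames = list(c("a", "a"), NULL))
  expect_error(convex_hull(dupnames), "duplicate")
})
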