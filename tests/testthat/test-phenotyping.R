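test_that("inter-landmark distances give k(k-1)/2 traits and known toy values", {
  set.seed(1)
  arr24 <- array(rnorm(5 * 24 * 3), dim = c(5, 24, 3))
  expect_equal(n_traits(interlandmark_distances(arr24)), 276L)
  arr5 <- array(rnorm(5 * 5 * 3), dim = c(5, 5, 3))
  expect_equal(n_traits(interlandmark_distances(arr5)), 10L)

  tri <- array(0, dim = c(1, 3, 3))
  tri[, 2, 1] <- 1; tri[, 3, 2] <- 1       # unit right triangle
  d <- interlandmark_distances(tri)
  expect_equal(sort(d$values[1, ]), sort(c(1, 1, sqrt(2))), ignore_attr = TRUE)
  expect_error(interlandmark_distances(array(0, dim = c(2, 1, 3))), "at least 2")
})

test_that("coincident landmarks give zero distance; always-coincident pairs are rejected", {
  set.seed(40)
  arr <- array(rnorm(3 * 3 * 3), dim = c(3, 3, 3))
  arr[1, 2, ] <- arr[1, 1, ]                 # coincident pair in shape 1 only
  d <- interlandmark_distances(arr)
  expect_equal(unname(d$values[1, "d_lm01_lm02"]), 0)
  arr[, 2, ] <- arr[, 1, ]                   # coincident in every shape
  expect_error(interlandmark_distances(arr), "constant")
})

test_that("distances are invariant under rigid motion", {
  set.seed(2)
  arr <- array(rnorm(4 * 6 * 3), dim = c(4, 6, 3))
  d0 <- interlandmark_distances(arr)
  d1 <- interlandmark_distances(apply_rigid(arr, seed = 7))
  expect_lt(max(abs(d0$values - d1$values)), 1e-10)
})

test_that("PCA shape space matches the covariance eigen-oracle", {
  set.seed(3)
  X <- matrix(rnorm(54), 6, 9)
  sp <- fit_pca(X)
  ev <- eigen(cov(X), symmetric = TRUE)
  k <- ncol(sp$basis)
  expect_equal(sp$axis_variance, ev$values[seq_len(k)], tolerance = 1e-8)
  # scores match projection onto eigenvectors up to per-axis sign
  sc_or <- scale(X, scale = FALSE) %*% ev$vectors[, seq_len(k)]
  expect_equal(abs(sp$scores), abs(sc_or), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(sp$basis) - diag(k))), 1e-8)
  expect_true(all(diff(sp$axis_variance) <= 1e-10))
  # completeness: full reconstruction
  rec <- sp$scores %*% t(sp$basis)
  expect_lt(max(abs(rec - scale(X, scale = FALSE))), 1e-8)
  # in-sample score correlations vanish
  expect_lt(max(abs(cor(sp$scores)[upper.tri(diag(k))])), 1e-6)
})

test_that("rank-1 data loads entirely on the first component", {
  set.seed(4)
  X <- outer(rnorm(20), rnorm(7))
  sp <- fit_pca(X)
  expect_equal(ncol(sp$basis), 1L)
  expect_gt(sp$axis_variance[1] / sum(sp$axis_variance), 0.999)
})

test_that("parallel analysis retains 0 on noise, k on planted factors, 1 on rank-1 data", {
  kept_noise <- vapply(1:10, function(s) {
    set.seed(s)
    as.integer(parallel_analysis(matrix(rnorm(100 * 15), 100, 15),
                                 n_perm = 30, seed = 1000 + s))
  }, integer(1))
  expect_true(all(kept_noise <= 1L))

  set.seed(5)
  F3 <- matrix(rnorm(500 * 3), 500, 3)
  X <- F3 %*% matrix(rnorm(3 * 20), 3, 20) * 3 + matrix(rnorm(500 * 20), 500, 20)
  expect_equal(as.integer(parallel_analysis(X, n_perm = 30, seed = 6)), 3L)

  X1 <- outer(rnorm(50), rnorm(8))
  expect_equal(as.integer(parallel_analysis(X1, n_perm = 20, seed = 7)), 1L)
})

test_that("projection round-trips training data and zeroes the mean shape", {
  set.seed(8)
  X <- matrix(rnorm(40 * 12), 40, 12)
  sp <- fit_pca(X)
  expect_lt(max(abs(project_scores(X, sp) - sp$scores)), 1e-10)
  expect_lt(max(abs(project_scores(matrix(sp$mean_shape, 1), sp))), 1e-10)
  # hand projection on a 2-axis toy space
  toy <- list(mean_shape = c(1, 1, 0), basis = cbind(c(1, 0, 0), c(0, 1, 0)),
              axis_variance = c(2, 1), n_fit = 2)
  class(toy) <- "shape_space"
  expect_equal(as.vector(project_scores(matrix(c(3, 4, 9), 1), toy)), c(2, 3))
  expect_error(project_scores(matrix(0, 1, 5), sp), "dimension")
})

test_that("resemblance score honours its geometric identities", {
  v <- c(1, 2, -1); av <- c(1.5, 2, 0.5)
  expect_equal(resemblance_score(v, v, av), 0)
  expect_equal(resemblance_score(v, -v, av), 2)
  # Mahalanobis-orthogonal pair
  a <- c(1, 0, 0); b <- c(0, 1, 0)
  expect_equal(resemblance_score(a, b, av), 1)
  # scale invariance in either argument
  expect_equal(resemblance_score(3.7 * v, av * 2, av),
               resemblance_score(v, av * 0.1, av), tolerance = 1e-12)
  # symmetry
  expect_equal(resemblance_score(v, av, av), resemblance_score(av, v, av))
  expect_error(resemblance_score(c(0, 0, 0), v, av), "zero-length")
  expect_error(resemblance_score(v, v, c(1, 0, 1)), "positive")
})

test_that("resemblance matches an explicit whitening oracle", {
  set.seed(9)
  av <- runif(5, 0.5, 4)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    xw <- x / sqrt(av); yw <- y / sqrt(av)
    oracle <- 1 - sum(xw * yw) / sqrt(sum(xw^2) * sum(yw^2))
    expect_equal(resemblance_score(x, y, av), oracle, tolerance = 1e-12)
  }
})

test_that("random gestalt traits are reproducible, self-zero, and exhaustive at n_gestalts = N", {
  set.seed(10)
  sc <- matrix(rnorm(30 * 4), 30, 4)
  av <- apply(sc, 2, var)
  a <- random_gestalt_traits(sc, 6, av, seed = 11)
  b <- random_gestalt_traits(sc, 6, av, seed = 11)
  expect_identical(a$values, b$values)
  expect_equal(colSums(a$values == 0), rep(1L, 6), ignore_attr = TRUE)
  expect_equal(n_traits(random_gestalt_traits(sc, 30, av, seed = 12)), 30L)
  expect_error(random_gestalt_traits(sc, 31, av, seed = 1), "<= N")
})

test_that("extreme gestalts follow the brute-force norm ranking with index tie-breaks", {
  set.seed(13)
  sc <- matrix(rnorm(25 * 3), 25, 3)
  av <- c(4, 1, 0.25)
  eg <- extreme_gestalt_traits(sc, 1, av)
  norms <- sqrt(rowSums(sweep(sc, 2, sqrt(av), `/`)^2))
  expect_equal(eg$provenance$gestalt_row, which.max(norms))

  # equal whitened norms: first k by index
  eq <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  eg2 <- extreme_gestalt_traits(eq, 2, c(1, 1))
  expect_equal(eg2$provenance$gestalt_row, c(1L, 2L))

  # prefix stability
  e3 <- extreme_gestalt_traits(sc, 3, av)
  e5 <- extreme_gestalt_traits(sc, 5, av)
  expect_equal(e5$values[, 1:3], e3$values, ignore_attr = TRUE)
})

test_that("syndrome archetypes are group means of projected scores", {
  set.seed(14)
  X <- matrix(rnorm(30 * 9), 30, 9)
  sp <- fit_pca(X)
  labels <- rep(c("g1", "g2", "g3"), each = 10)
  arch <- syndrome_archetypes(mesh_config(unflatten_coords(X, 3)), labels, sp)
  sc <- project_scores(X, sp)
  expect_equal(arch["g2", ], colMeans(sc[11:20, ]), ignore_attr = TRUE)
  # single-member group: archetype equals that member's scores
  arch1 <- syndrome_archetypes(mesh_config(unflatten_coords(X[1:11, ], 3)),
                               c("solo", rep("rest", 10)), sp)
  expect_equal(arch1["solo", ], sc[1, ], ignore_attr = TRUE)
  # exact cancellation puts the archetype at the mean face: resemblance errors
  cancel <- rbind(sc[1, ], -sc[1, ])
  expect_equal(colMeans(cancel), rep(0, ncol(sc)), ignore_attr = TRUE)
  expect_error(resemblance_score(sc[2, ], colMeans(cancel), sp$axis_variance),
               "zero-length")
})

test_that("archetype distinctness test is calibrated and saturates under large shifts", {
  set.seed(15)
  # type-I: archetype group drawn from the control distribution
  rejections <- vapply(1:200, function(s) {
    set.seed(2000 + s)
    g <- matrix(rnorm(8 * 3), 8, 3)
    ctrl <- matrix(rnorm(20 * 3), 20, 3)
    as.numeric(archetype_distinctness_test(g, ctrl, n_perm = 99,
                                           seed = 3000 + s)) <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.01); expect_lt(rate, 0.11)

  # saturated shift: 5 control SD
  g <- matrix(rnorm(10 * 3), 10, 3) + 5
  ctrl <- matrix(rnorm(30 * 3), 30, 3)
  p <- archetype_distinctness_test(g, ctrl, n_perm = 199, seed = 16)
  expect_equal(as.numeric(p), 1 / 200)
  # p-value floor arithmetic at n_perm = 99
  p99 <- archetype_distinctness_test(g, ctrl, n_perm = 99, seed = 17)
  expect_equal(as.numeric(p99), 0.01)
  expect_error(archetype_distinctness_test(g, ctrl, n_perm = 50), "n_perm")
})

test_that("syndrome gestalt traits drop indistinct archetypes", {
  tmpl <- tiny_template()
  basis <- make_shape_basis(tmpl, 3, seed = 18)
  sy <- simulate_syndromic_groups(tmpl, basis, 2, c(6, 0), n_per_group = 25,
                                  n_controls = 25, seed = 19)
  fx <- tiny_cohort(n = 80, seed = 20)
  space <- fit_pca(fx$cohort$meshes)
  k <- min(5L, ncol(space$basis))
  space$basis <- space$basis[, 1:k, drop = FALSE]
  space$axis_variance <- space$axis_variance[1:k]
  space$scores <- space$scores[, 1:k, drop = FALSE]
  ts <- syndrome_gestalt_traits(space$scores, sy, space, n_perm = 199, seed = 21)
  expect_equal(ts$provenance$group, "syndrome1")
  expect_true(all(ts$provenance$p_distinct <= 0.05))
})
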