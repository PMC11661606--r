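test_that("GPA leaves identical copies untouched and undoes rigid motion", {
  tmpl <- tiny_template()
  x <- tmpl$mesh$coords[1, , ]
  copies <- mesh_config(array(rep(x, each = 4), dim = c(4, nrow(x), 3)))
  g <- gpa_align(copies)
  expect_lt(tail(g$ss, 1), 1e-16)
  expect_equal(g$centroid_size, rep(centroid_size(x), 4))

  moved <- mesh_config(array(rep(x, each = 2), dim = c(2, nrow(x), 3)))
  moved$coords[2, , ] <- apply_rigid(moved$coords[2, , , drop = FALSE], seed = 3)[1, , ]
  a <- gpa_align(moved)
  expect_lt(max(abs(a$meshes$coords[1, , ] - a$meshes$coords[2, , ])), 1e-8)
})

test_that("GPA objective is non-increasing and matches a brute-force oracle", {
  set.seed(11)
  base <- matrix(rnorm(12), 4, 3)
  arr <- array(0, dim = c(3, 4, 3))
  for (i in 1:3) arr[i, , ] <- base + matrix(rnorm(12, 0, 0.3), 4, 3)
  arr <- apply_rigid(arr, seed = 5)
  g <- gpa_align(mesh_config(arr))
  expect_true(all(diff(g$ss) <= 1e-10))

  # oracle: direct minimization of the Procrustes objective over Euler
  # angles of all three configurations
  centred <- lapply(1:3, function(i) sweep(arr[i, , ], 2, colMeans(arr[i, , ])))
  obj <- function(par) {
    rots <- lapply(1:3, function(i) euler_rotation(par[(3 * i - 2):(3 * i)]))
    xs <- Map(`%*%`, centred, rots)
    cons <- Reduce(`+`, xs) / 3
    sum(vapply(xs, function(x) sum((x - cons)^2), numeric(1)))
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    fit <- optim(runif(9, -pi, pi), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  expect_equal(tail(g$ss, 1), best, tolerance = 1e-6)
})

test_that("GPA rejects degenerate configurations", {
  flat <- mesh_config(array(1, dim = c(3, 5, 3)))
  expect_error(gpa_align(flat), "degenerate")
})

test_that("symmetrization fixes symmetric shapes, is idempotent, and matches the hand formula", {
  tmpl <- tiny_template()
  s0 <- symmetrize(tmpl$mesh)
  expect_equal(s0$coords, tmpl$mesh$coords, tolerance = 1e-12)

  fx <- tiny_cohort(n = 10)
  noisy <- fx$cohort$meshes
  noisy$coords <- noisy$coords + array(rnorm(length(noisy$coords)), dim = dim(noisy$coords))
  s1 <- symmetrize(noisy)
  s2 <- symmetrize(s1)
  expect_equal(s1$coords, s2$coords, tolerance = 1e-12)
  # mirror invariance to 1e-10
  refl <- s1$coords[, s1$mirror_map, , drop = FALSE]
  refl[, , 1] <- -refl[, , 1]
  expect_lt(max(abs(s1$coords - refl)), 1e-10)

  # 4-point toy with pairing (1<->2, 3<->3, 4<->4): hand computation
  pts <- rbind(c(1, 0, 0), c(-2, 1, 0), c(0, 2, 1), c(0, -1, 3))
  toy <- mesh_config(array(pts, dim = c(1, 4, 3)), mirror_map = c(2, 1, 3, 4))
  sy <- symmetrize(toy)
  expect_equal(sy$coords[1, 1, ], c((1 + 2) / 2, (0 + 1) / 2, 0))
  expect_equal(sy$coords[1, 2, ], c((-2 - 1) / 2, (1 + 0) / 2, 0))
  expect_equal(sy$coords[1, 3, ], c(0, 2, 1))
  expect_error(symmetrize(toy, mirror_map = c(2, 3, 1, 4)), "involution")
})

test_that("PLS adjustment reduces to OLS in the full-component limit", {
  set.seed(21)
  n <- 60; L <- 15
  covars <- data.frame(a = rnorm(n), b = rnorm(n), c = runif(n))
  Y <- matrix(rnorm(n * 3 * L), n, 3 * L)
  Y <- Y + as.matrix(covars) %*% matrix(rnorm(3 * 3 * L), 3, 3 * L)
  meshes <- mesh_config(unflatten_coords(Y, L))
  adj <- adjust_covariates_pls(meshes, covars)
  res <- flatten_coords(adj$coords)
  ols <- qr.resid(qr(cbind(1, as.matrix(covars))), Y)
  expect_lt(max(abs(res - ols)), 1e-6)
  expect_lt(max(abs(colMeans(res))), 1e-8)
  # residuals orthogonal to the covariates
  expect_lt(max(abs(crossprod(scale(as.matrix(covars), scale = FALSE), res))), 1e-6)
})

test_that("PLS adjustment leaves shape untouched when covariates are unrelated, removes it when exact", {
  set.seed(22)
  n <- 500; L <- 6
  covars <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 3 * L), n, 3 * L)
  adj <- adjust_covariates_pls(mesh_config(unflatten_coords(Y, L)), covars)
  Yc <- scale(Y, scale = FALSE)
  # residuals close to the centred input (loadings ~ 0)
  expect_lt(mean((flatten_coords(adj$coords) - Yc)^2) / mean(Yc^2), 0.02)

  Ylin <- as.matrix(covars) %*% matrix(rnorm(2 * 3 * L), 2, 3 * L)
  adj2 <- adjust_covariates_pls(mesh_config(unflatten_coords(Ylin, L)), covars,
                                n_components = 2)
  expect_lt(max(abs(flatten_coords(adj2$coords))), 1e-8)
})

test_that("rank-deficient covariates trigger a warning and reduced components", {
  set.seed(23)
  covars <- data.frame(a = rnorm(30), b = rnorm(30))
  covars$c <- covars$a + covars$b
  Y <- matrix(rnorm(30 * 9), 30, 9)
  expect_warning(adjust_covariates_pls(mesh_config(unflatten_coords(Y, 3)),
                                       covars, n_components = 3), "rank")
})

test_that("RV coefficient matches the trace formula and its limits", {
  set.seed(31)
  A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(15), 5, 3)
  # brute-force trace computation
  Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
  sab <- crossprod(Ac, Bc); saa <- crossprod(Ac); sbb <- crossprod(Bc)
  oracle <- sum(diag(sab %*% t(sab))) / sqrt(sum(diag(saa %*% saa)) * sum(diag(sbb %*% sbb)))
  expect_equal(rv_coefficient(A, B), oracle, tolerance = 1e-12)
  expect_equal(rv_coefficient(A, B), rv_coefficient(B, A))
  expect_equal(rv_coefficient(A, A), 1)
  expect_gte(rv_coefficient(A, B), 0)
  expect_lte(rv_coefficient(A, B), 1)

  A2 <- matrix(rnorm(5000 * 3), 5000, 3); B2 <- matrix(rnorm(5000 * 3), 5000, 3)
  expect_lt(rv_coefficient(A2, B2), 0.1)
  expect_error(rv_coefficient(matrix(0, 5, 2), B), "zero-variance")
})

test_that("spectral segmentation recovers planted vertex communities", {
  set.seed(41)
  n <- 150; L <- 12
  f1 <- rnorm(n); f2 <- rnorm(n)
  coords <- array(rnorm(n * L * 3, 0, 0.3), dim = c(n, L, 3))
  for (v in 1:6) coords[, v, ] <- coords[, v, ] + f1
  for (v in 7:12) coords[, v, ] <- coords[, v, ] + f2
  labs <- segment_hierarchical(mesh_config(coords), n_levels = 1)
  split <- labs[, "level1"]
  tab <- table(split, rep(c("a", "b"), each = 6))
  # perfect recovery: each cluster maps to one community
  expect_equal(sort(as.vector(tab)), c(0, 0, 6, 6))

  labs0 <- segment_hierarchical(mesh_config(coords), n_levels = 0)
  expect_equal(unique(labs0[, "level0"]), "0")
  labs_b <- segment_hierarchical(mesh_config(coords), n_levels = 1)
  expect_identical(labs, labs_b)
  # refinement: level-2 labels refine level-1 labels
  labs2 <- segment_hierarchical(mesh_config(coords), n_levels = 2)
  expect_true(all(startsWith(labs2[, "level2"], labs2[, "level1"])))
  expect_error(segment_hierarchical(mesh_config(coords), n_levels = -1), "n_levels")
})
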