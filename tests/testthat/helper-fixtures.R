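# Small shared fixtures, built in code at test time.

tiny_template <- function() face_template(n_polar = 8L, n_lateral = 7L)

tiny_cohort <- function(n = 120L, m = 60L, seed = 42L, h2 = 0.6,
                        causal = c(10L, 40L), k = 4L) {
  tmpl <- tiny_template()
  basis <- make_shape_basis(tmpl, k, seed = seed)
  panel <- simulate_genotypes(n, m, block_size = 10L, seed = seed + 1L)
  arch <- architecture_spec(
    effects = data.frame(snp = causal, axis = seq_along(causal), beta = 1),
    h2_target = h2, seed = seed + 2L)
  covars <- make_covariates(n, panel$cohort, seed = seed + 3L)
  cohort <- simulate_cohort(panel, arch, tmpl, basis, covariates = covars)
  list(tmpl = tmpl, basis = basis, panel = panel, arch = arch,
       covars = cohort$covariates, cohort = cohort)
}

# random rigid motion applied to an N x k x 3 landmark array
apply_rigid <- function(arr, seed = 1L) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  shift <- rnorm(3, 0, 10)
  out <- arr
  for (i in seq_len(dim(arr)[1]))
    out[i, , ] <- sweep(arr[i, , , drop = TRUE] %*% R, 2L, -shift)
  out
}

euler_rotation <- function(ang) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}
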