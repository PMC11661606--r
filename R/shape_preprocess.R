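#' Generalized Procrustes alignment
#'
#' Iterative Procrustes superimposition with translation and rotation only
#' (no reflection, no scaling): shapes are centred, each is rotated to the
#' running consensus by the orthogonal Procrustes solution constrained to
#' `det(R) = +1`, and the consensus is recomputed until the Procrustes sum
#' of squares stabilizes.  Size is deliberately not removed; the centroid
#' size of every raw shape is returned so it can be adjusted for as the
#' "facial size" covariate downstream.
#'
#' @param meshes a [mesh_config] with `N >= 2` shapes.
#' @param max_iter,tol iteration cap and relative tolerance on the
#'   Procrustes sum of squares.
#' @return list with `meshes` (aligned [mesh_config], consensus centroid at
#'   the origin), `centroid_size` (length-`N`), `consensus` (`L x 3`), and
#'   `ss` (per-iteration Procrustes sum of squares, non-increasing).
#' @export
gpa_align <- function(meshes, max_iter = 100L, tol = 1e-10) {
  x <- meshes$coords
  n <- dim(x)[1]; L <- dim(x)[2]
  if (n < 2L) stop_arg("GPA needs at least 2 shapes")
  csize <- apply(x, 1L, centroid_size)
  if (any(csize < .Machine$double.eps * L))
    stop_arg("degenerate configuration: all vertices coincident")
  for (i in seq_len(n)) x[i, , ] <- sweep(x[i, , ], 2L, colMeans(x[i, , ]))
  consensus <- x[1L, , ]                 # anchor on the first shape, then iterate
  ss_path <- numeric(0)
  ss_old <- Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) x[i, , ] <- x[i, , ] %*% rotation_to(x[i, , ], consensus)
    consensus <- apply(x, c(2L, 3L), mean)
    ss <- sum(sweep(x, c(2L, 3L), consensus)^2)
    ss_path <- c(ss_path, ss)
    if (is.finite(ss_old) && ss_old - ss <= tol * max(ss_old, 1)) break
    ss_old <- ss
  }
  list(meshes = mesh_config(x, mirror_map = meshes$mirror_map,
                            vertex_ids = meshes$vertex_ids),
       centroid_size = csize, consensus = consensus, ss = ss_path)
}

# Rotation (proper orthogonal, det = +1) minimizing ||a %*% R - b||_F for
# centred configurations a, b (Kabsch).
rotation_to <- function(a, b) {
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Symmetrize shape configurations
#'
#' Replaces every shape by the average of itself and its reflected,
#' relabelled image: `sym(x) = (x + P reflect(x)) / 2`, where `reflect`
#' negates the lateral (x) coordinate and `P` permutes each vertex to its
#' bilateral partner.  The result is invariant under the mirror operation
#' and the map is idempotent.
#'
#' @param meshes a [mesh_config].
#' @param mirror_map involutory vertex permutation; defaults to the one
#'   stored in `meshes`.
#' @return symmetrized [mesh_config].
#' @export
symmetrize <- function(meshes, mirror_map = meshes$mirror_map) {
  if (is.null(mirror_map)) stop_arg("no mirror map available")
  L <- n_vertices(meshes)
  mirror_map <- as.integer(mirror_map)
  if (length(mirror_map) != L || !identical(mirror_map[mirror_map], seq_len(L)))
    stop_arg("`mirror_map` must be an involution on 1:L")
  refl <- meshes$coords[, mirror_map, , drop = FALSE]
  refl[, , 1L] <- -refl[, , 1L]
  mesh_config((meshes$coords + refl) / 2, mirror_map = mirror_map,
              vertex_ids = meshes$vertex_ids)
}

#' Adjust shapes for covariates by PLS regression
#'
#' Regresses the flattened vertex coordinates on the covariate table by
#' partial least squares and returns the residual shapes (deviations from
#' the fitted values; residual column means are ~0).  With
#' `n_components` equal to the covariate-design rank, PLS spans the full
#' covariate column space and the residuals coincide with ordinary
#' least-squares residuals.
#'
#' @param meshes a [mesh_config].
#' @param covariates data.frame or numeric matrix of covariates (factors
#'   are expanded to dummies); constant columns are dropped.
#' @param n_components number of PLS components; default (and maximum) is
#'   the rank of the covariate design.  Rank-deficient designs trigger a
#'   warning and a reduced component count.
#' @param keep_mean add the mean shape back onto the residuals so the output
#'   stays face-like (useful before anthropometric traits); the default
#'   returns pure residual deviations with column means ~0.
#' @return a [mesh_config] of residual shapes.
#' @export
adjust_covariates_pls <- function(meshes, covariates, n_components = NULL,
                                  keep_mean = FALSE) {
  X <- covariate_matrix(covariates)
  Y <- flatten_coords(meshes$coords)
  n <- nrow(Y)
  if (nrow(X) != n) stop_arg("covariate rows must match the number of shapes")
  rk <- qr(scale(X, scale = FALSE))$rank
  if (is.null(n_components)) n_components <- rk
  if (n_components > rk) {
    warning(sprintf("covariate design has rank %d; reducing n_components from %d",
                    rk, n_components))
    n_components <- rk
  }
  if (n_components > ncol(X)) stop_arg("`n_components` exceeds the number of covariates")
  fit <- simpls_fit(X, Y, n_components)
  res <- Y - fit$fitted
  if (keep_mean) res <- sweep(res, 2L, colMeans(Y), `+`)
  dimnames(res) <- NULL
  mesh_config(unflatten_coords(res, n_vertices(meshes)),
              mirror_map = meshes$mirror_map, vertex_ids = meshes$vertex_ids)
}

# Numeric covariate design: expand factors, drop constant columns.
covariate_matrix <- function(covariates) {
  if (is.matrix(covariates)) {
    X <- covariates
  } else {
    X <- model.matrix(~ ., data = as.data.frame(covariates))[, -1L, drop = FALSE]
  }
  keep <- apply(X, 2L, function(v) sd(v) > 0)
  X[, keep, drop = FALSE]
}

#' Escoufier's RV coefficient
#'
#' Matrix correlation between two multivariate blocks observed on the same
#' individuals: `RV = tr(S_AB S_BA) / sqrt(tr(S_AA^2) tr(S_BB^2))`, with
#' `S` the (cross-)covariance blocks of the column-centred data.  Lies in
#' `[0, 1]` and is symmetric in its arguments.
#'
#' @param a,b numeric matrices with the same number of rows (`N >= 3`).
#' @return scalar RV coefficient.
#' @export
rv_coefficient <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || nrow(a) < 3L) stop_arg("blocks must share N >= 3 rows")
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  saa <- sum(crossprod(ac)^2); sbb <- sum(crossprod(bc)^2)
  if (saa <= 0 || sbb <= 0) stop_arg("zero-variance block")
  sum(crossprod(ac, bc)^2) / sqrt(saa * sbb)
}

#' Hierarchical spectral segmentation of vertices
#'
#' Groups strongly covarying vertices: the similarity between two vertices
#' is the RV coefficient between their `N x 3` coordinate blocks across
#' shapes, and segments are formed by recursive two-way spectral
#' bipartition (sign of the Fiedler vector of the normalized Laplacian) to
#' `n_levels` levels.  Labels at level `d + 1` refine labels at level `d`
#' by construction.
#'
#' @param meshes a [mesh_config].
#' @param n_levels number of bipartition levels (>= 0); level 0 is the
#'   whole-surface segment.
#' @param min_size segments smaller than this are not subdivided further.
#' @return character matrix `L x (n_levels + 1)` of segment labels, columns
#'   `level0 ... level<n_levels>`; attribute `"similarity"` holds the
#'   vertex RV matrix.
#' @export
segment_hierarchical <- function(meshes, n_levels, min_size = 4L) {
  if (n_levels < 0L) stop_arg("`n_levels` must be >= 0")
  L <- n_vertices(meshes)
  X <- scale(flatten_coords(meshes$coords), scale = FALSE)
  C2 <- (crossprod(X) / (nrow(X) - 1))^2
  G <- matrix(0, 3L * L, L)
  G[cbind(seq_len(3L * L), rep(seq_len(L), each = 3L))] <- 1
  S <- crossprod(G, C2 %*% G)                 # sum of squared 3x3 block entries
  d <- sqrt(diag(S))
  sim <- S / tcrossprod(pmax(d, .Machine$double.eps))
  labels <- matrix("0", L, n_levels + 1L)
  colnames(labels) <- paste0("level", 0:n_levels)
  recurse <- function(idx, path, level) {
    if (level > n_levels) return()
    if (length(idx) < min_size) {
      labels[idx, (level:n_levels) + 1L] <<- path
      return()
    }
    side <- fiedler_split(sim[idx, idx, drop = FALSE])
    if (all(side) || all(!side)) {            # degenerate cut: keep segment whole
      labels[idx, (level:n_levels) + 1L] <<- path
      return()
    }
    l0 <- idx[side]; l1 <- idx[!side]
    labels[l0, level + 1L] <<- paste0(path, "0")
    labels[l1, level + 1L] <<- paste0(path, "1")
    recurse(l0, paste0(path, "0"), level + 1L)
    recurse(l1, paste0(path, "1"), level + 1L)
  }
  if (n_levels >= 1L) recurse(seq_len(L), "0", 1L)
  labels
}

# Sign split on the Fiedler vector of the symmetric normalized Laplacian.
# Deterministic: the vector is oriented so its first entry of largest
# magnitude is positive; near-zero entries join the side of vertex 1.
fiedler_split <- function(sim) {
  m <- nrow(sim)
  d <- pmax(rowSums(sim), .Machine$double.eps)
  Lsym <- diag(m) - sim / sqrt(tcrossprod(d))
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  f <- e$vectors[, m - 1L]                     # second-smallest eigenvalue
  if (f[which.max(abs(f))] < 0) f <- -f
  tol <- 1e-12 * max(abs(f))
  side <- f > tol
  side[abs(f) <= tol] <- side[1L] %in% TRUE || sum(side) == 0L
  side
}
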