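#' Univariate trait sets
#'
#' An `N x T` matrix of univariate phenotypes plus its category label (one
#' of `DISTANCE`, `PCA`, `AE`, `RANDOM`, `EXTREME`, `SYNDROME`), trait ids,
#' provenance, and the seed for stochastic families.
#'
#' @param values numeric `N x T` matrix.
#' @param category trait family label.
#' @param trait_ids character trait identifiers.
#' @param provenance optional data.frame describing each trait (landmark
#'   pair, PC index, gestalt id, ...).
#' @param seed seed used to generate the traits, where stochastic.
#' @return an object of class `trait_set`.
#' @export
trait_set <- function(values, category, trait_ids = colnames(values),
                      provenance = NULL, seed = NULL) {
  category <- match.arg(category,
                        c("DISTANCE", "PCA", "AE", "RANDOM", "EXTREME", "SYNDROME"))
  values <- as.matrix(values)
  if (is.null(trait_ids)) trait_ids <- sprintf("%s%03d", tolower(category), seq_len(ncol(values)))
  constant <- if (nrow(values) >= 2L) apply(values, 2L, sd) == 0
              else rep(FALSE, ncol(values))
  if (any(constant))
    stop_arg("constant trait column(s): ", paste(trait_ids[constant], collapse = ", "))
  colnames(values) <- trait_ids
  structure(list(values = values, category = category, trait_ids = trait_ids,
                 provenance = provenance, seed = seed),
            class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat(sprintf("trait_set [%s]: %d individuals x %d traits\n",
              x$category, nrow(x$values), ncol(x$values)))
  invisible(x)
}

n_traits <- function(ts) ncol(ts$values)

# Subset a trait family by column, keeping metadata coherent.
subset_traits <- function(ts, cols) {
  trait_set(ts$values[, cols, drop = FALSE], ts$category,
            trait_ids = ts$trait_ids[cols],
            provenance = if (!is.null(ts$provenance)) ts$provenance[cols, , drop = FALSE],
            seed = ts$seed)
}

#' Inter-landmark distance traits
#'
#' One trait per unordered landmark pair: the 3D Euclidean distance, giving
#' `k(k-1)/2` traits for `k` landmarks (276 for 24 landmarks, 10 for 5).
#'
#' @param landmarks numeric `N x k x 3` array of landmark coordinates, or a
#'   [mesh_config] plus `which` indices.
#' @param which optional vertex indices selecting landmarks from a
#'   [mesh_config].
#' @return a `trait_set` of category `DISTANCE`.
#' @export
interlandmark_distances <- function(landmarks, which = NULL) {
  if (inherits(landmarks, "mesh_config")) {
    if (is.null(which)) stop_arg("supply `which` vertex indices with a mesh_config")
    landmarks <- landmarks$coords[, which, , drop = FALSE]
  }
  k <- dim(landmarks)[2]
  if (is.null(k) || k < 2L) stop_arg("need at least 2 landmarks")
  nm <- dimnames(landmarks)[[2]] %||% sprintf("lm%02d", seq_len(k))
  pairs <- combn(k, 2L)
  n <- dim(landmarks)[1]
  vals <- apply(pairs, 2L, function(pr) {
    d <- landmarks[, pr[1], , drop = FALSE] - landmarks[, pr[2], , drop = FALSE]
    sqrt(rowSums(matrix(d, nrow = n)^2))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  ids <- apply(pairs, 2L, function(pr) paste0("d_", nm[pr[1]], "_", nm[pr[2]]))
  prov <- data.frame(landmark_a = nm[pairs[1, ]], landmark_b = nm[pairs[2, ]])
  trait_set(vals, "DISTANCE", trait_ids = ids, provenance = prov)
}

#' Principal component shape space
#'
#' Singular value decomposition of the mean-centred `N x 3L` shape matrix
#' `X = U D V'`: the right singular vectors form the orthonormal basis, the
#' per-axis score variances come from the singular values, and the scores
#' (`U D`) are mutually uncorrelated.
#'
#' @param meshes a [mesh_config] or numeric `N x p` matrix.
#' @param tol relative singular-value cutoff below which trailing axes are
#'   dropped.
#' @return an object of class `shape_space` with fields `mean_shape`,
#'   `basis` (`p x K`, orthonormal), `axis_variance` (non-increasing),
#'   `scores` (`N x K`) and `n_fit`.
#' @export
fit_pca <- function(meshes, tol = 1e-10) {
  X <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  n <- nrow(X)
  if (n < 2L) stop_arg("need at least 2 shapes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
  keep <- s$d > tol * s$d[1]
  K <- sum(keep)
  structure(list(mean_shape = mu,
                 basis = s$v[, seq_len(K), drop = FALSE],
                 axis_variance = s$d[seq_len(K)]^2 / (n - 1),
                 scores = s$u[, seq_len(K), drop = FALSE] %*% diag(s$d[seq_len(K)], K),
                 n_fit = n),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape_space: %d axes fitted on %d shapes (leading variance %.3g)\n",
              ncol(x$basis), x$n_fit, x$axis_variance[1]))
  invisible(x)
}

#' Scores of a trait family as a `trait_set`
#'
#' @param space a [fit_pca()] shape space.
#' @param k number of leading components to keep as traits.
#' @return a `trait_set` of category `PCA`.
#' @export
pca_traits <- function(space, k = ncol(space$basis)) {
  k <- min(k, ncol(space$scores))
  trait_set(space$scores[, seq_len(k), drop = FALSE], "PCA",
            trait_ids = sprintf("PC%03d", seq_len(k)),
            provenance = data.frame(component = seq_len(k)))
}

#' Parallel analysis for component retention
#'
#' Compares observed per-component score variances with the 95th percentile
#' of variances obtained after independently permuting every column of the
#' centred data (Horn's procedure); the retained count is the number of
#' leading components whose variance exceeds its permutation threshold.
#'
#' @param meshes a [mesh_config] or numeric matrix.
#' @param n_perm number of permutations (>= 20).
#' @param quantile_level percentile of the null variances (default 0.95).
#' @param seed RNG seed.
#' @return integer retained component count, with attribute `"thresholds"`.
#' @export
parallel_analysis <- function(meshes, n_perm = 50L, quantile_level = 0.95,
                              seed = NULL) {
  if (n_perm < 20L) stop_arg("`n_perm` must be >= 20")
  X <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  obs <- svd(Xc, nu = 0L, nv = 0L)$d^2 / (n - 1)
  kmax <- length(obs)
  with_seed(seed, {
    null_var <- matrix(0, n_perm, kmax)
    for (b in seq_len(n_perm)) {
      P <- apply(Xc, 2L, sample)
      null_var[b, ] <- svd(P, nu = 0L, nv = 0L)$d[seq_len(kmax)]^2 / (n - 1)
    }
    thr <- apply(null_var, 2L, quantile, probs = quantile_level, names = FALSE)
    exceeds <- obs > thr
    first_fail <- which(!exceeds)[1L]
    retained <- if (is.na(first_fail)) kmax else first_fail - 1L
    structure(as.integer(retained), thresholds = thr, observed = obs)
  })
}

#' Project shapes into a shape space
#'
#' `scores = (flattened shape - mean_shape) %*% basis`; projecting the
#' training data reproduces the fitted scores, and the mean shape projects
#' to the zero vector.
#'
#' @param meshes a [mesh_config] or numeric matrix with matching columns.
#' @param space a [fit_pca()] shape space.
#' @return numeric `N x K` score matrix.
#' @export
project_scores <- function(meshes, space) {
  X <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  if (ncol(X) != length(space$mean_shape))
    stop_arg("vertex dimension does not match the shape space")
  sweep(X, 2L, space$mean_shape) %*% space$basis
}

#' Resemblance score between two faces
#'
#' One minus the cosine of the Mahalanobis angle: both score vectors are
#' standardized by the per-axis standard deviation of the shape space and
#' the cosine of the angle between the whitened vectors is subtracted from
#' one.  The score lies in `[0, 2]`: 0 for identical directions, 1 for
#' Mahalanobis-orthogonal vectors, 2 for antipodal ones; it is invariant
#' under positive rescaling of either vector.  Note the orientation: despite
#' the name, larger values mean less resemblance.
#'
#' @param sample_scores,target_scores length-`K` score vectors.
#' @param axis_variance positive per-axis variances used for whitening.
#' @return scalar in `[0, 2]`.
#' @export
resemblance_score <- function(sample_scores, target_scores, axis_variance) {
  if (any(axis_variance <= 0)) stop_arg("`axis_variance` must be positive")
  w <- 1 / sqrt(axis_variance)
  u <- sample_scores * w; v <- target_scores * w
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_arg("angle undefined: zero-length vector at the mean face")
  1 - sum(u * v) / (nu * nv)
}

# Whiten score rows and compute all resemblance scores to the given target
# rows in one pass; returns N x T matrix.
resemblance_matrix <- function(scores, target_scores, axis_variance) {
  w <- 1 / sqrt(axis_variance)
  U <- sweep(scores, 2L, w, `*`)
  V <- sweep(target_scores, 2L, w, `*`)
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  if (any(nu == 0) || any(nv == 0))
    stop_arg("angle undefined: zero-length score vector at the mean face")
  1 - (U %*% t(V)) / outer(nu, nv)
}

#' Resemblance traits to random facial gestalts
#'
#' Draws `n_gestalts` cohort members uniformly without replacement; trait
#' `t` scores every individual's resemblance to gestalt `t`.  A gestalt's
#' resemblance to itself is exactly 0.
#'
#' @param scores `N x K` face-space scores of the cohort.
#' @param n_gestalts number of gestalts (<= N).
#' @param axis_variance per-axis variances for whitening.
#' @param seed RNG seed.
#' @return a `trait_set` of category `RANDOM`; provenance records the
#'   sampled gestalt row indices.
#' @export
random_gestalt_traits <- function(scores, n_gestalts, axis_variance, seed = NULL) {
  n <- nrow(scores)
  if (n_gestalts > n) stop_arg("`n_gestalts` must be <= N")
  with_seed(seed, {
    idx <- sample.int(n, n_gestalts)
    vals <- resemblance_matrix(scores, scores[idx, , drop = FALSE], axis_variance)
    vals[cbind(idx, seq_len(n_gestalts))] <- 0
    trait_set(vals, "RANDOM",
              trait_ids = sprintf("RND%03d", seq_len(n_gestalts)),
              provenance = data.frame(gestalt_row = idx), seed = seed)
  })
}

#' Resemblance traits to extreme facial gestalts
#'
#' Ranks individuals by the Mahalanobis norm of their score vector
#' (descending; ties broken by ascending row index) and uses the top
#' `n_gestalts` most peripheral faces as gestalts.
#'
#' @inheritParams random_gestalt_traits
#' @return a `trait_set` of category `EXTREME`; provenance records gestalt
#'   row indices and their whitened norms, in rank order.
#' @export
extreme_gestalt_traits <- function(scores, n_gestalts, axis_variance) {
  n <- nrow(scores)
  if (n_gestalts > n) stop_arg("`n_gestalts` must be <= N")
  norms <- sqrt(rowSums(sweep(scores, 2L, sqrt(axis_variance), `/`)^2))
  ord <- order(-norms, seq_len(n))
  idx <- ord[seq_len(n_gestalts)]
  vals <- resemblance_matrix(scores, scores[idx, , drop = FALSE], axis_variance)
  vals[cbind(idx, seq_len(n_gestalts))] <- 0
  trait_set(vals, "EXTREME",
            trait_ids = sprintf("EXT%03d", seq_len(n_gestalts)),
            provenance = data.frame(gestalt_row = idx, mahalanobis_norm = norms[idx]))
}

#' Syndromic archetypes in a shape space
#'
#' Projects syndromic shapes into the cohort shape space and returns the
#' mean score vector (archetype) of each group.
#'
#' @param syndromic_meshes a [mesh_config] of syndromic shapes.
#' @param labels group label per shape (controls allowed; every level must
#'   be non-empty).
#' @param space the cohort [fit_pca()] shape space.
#' @return `G x K` matrix of archetype score vectors, rownames = groups.
#' @export
syndrome_archetypes <- function(syndromic_meshes, labels, space) {
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop_arg("empty syndrome group")
  sc <- project_scores(syndromic_meshes, space)
  arch <- rowsum(sc, labels) / as.vector(table(labels))
  arch
}

#' Permutation test of archetype distinctness
#'
#' Tests whether a syndromic group's mean projected shape differs from the
#' control mean.  The statistic is the Mahalanobis norm (whitened by
#' `axis_variance`) of the difference between the group archetype and the
#' control mean; the null is built by permuting group/control labels and
#' recomputing, and `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param group_scores `n_g x K` projected scores of the syndromic group.
#' @param control_scores `n_c x K` projected scores of the controls
#'   (`n_c >= 2`).
#' @param axis_variance per-axis variances for whitening (default: all 1).
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return p-value with attribute `"statistic"`.
#' @export
archetype_distinctness_test <- function(group_scores, control_scores,
                                        axis_variance = NULL, n_perm = 999L,
                                        seed = NULL) {
  if (n_perm < 99L) stop_arg("`n_perm` must be >= 99")
  group_scores <- as.matrix(group_scores); control_scores <- as.matrix(control_scores)
  if (nrow(control_scores) < 2L) stop_arg("need at least 2 controls")
  K <- ncol(group_scores)
  axis_variance <- axis_variance %||% rep(1, K)
  w <- 1 / sqrt(axis_variance)
  stat <- function(g, c) sqrt(sum(((colMeans(g) - colMeans(c)) * w)^2))
  obs <- stat(group_scores, control_scores)
  pool <- rbind(group_scores, control_scores)
  ng <- nrow(group_scores); ntot <- nrow(pool)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(b) {
      pick <- sample.int(ntot, ng)
      stat(pool[pick, , drop = FALSE], pool[-pick, , drop = FALSE])
    }, numeric(1))
    structure((1 + sum(null >= obs)) / (1 + n_perm), statistic = obs)
  })
}

#' Resemblance traits to syndromic archetypes
#'
#' Projects syndromic groups, keeps the archetypes that pass the
#' distinctness test at `alpha`, and scores every cohort member's
#' resemblance to each retained archetype.
#'
#' @param scores cohort `N x K` face-space scores.
#' @param syndromic a list as returned by [simulate_syndromic_groups()]
#'   (fields `meshes` and `labels`, with a `"control"` level).
#' @param space the cohort shape space.
#' @param alpha distinctness threshold; archetypes with `p > alpha` are
#'   dropped.
#' @param n_perm,seed permutation settings for the distinctness test.
#' @return a `trait_set` of category `SYNDROME`; provenance records group
#'   names and distinctness p-values of the retained archetypes.
#' @export
syndrome_gestalt_traits <- function(scores, syndromic, space, alpha = 0.05,
                                    n_perm = 999L, seed = NULL) {
  labels <- as.factor(syndromic$labels)
  if (!"control" %in% levels(labels)) stop_arg("syndromic data needs a control group")
  sc <- project_scores(syndromic$meshes, space)
  ctrl <- sc[labels == "control", , drop = FALSE]
  groups <- setdiff(levels(labels), "control")
  pvals <- vapply(groups, function(g) {
    as.numeric(archetype_distinctness_test(sc[labels == g, , drop = FALSE], ctrl,
                                           axis_variance = space$axis_variance,
                                           n_perm = n_perm, seed = seed))
  }, numeric(1))
  keep <- groups[pvals <= alpha]
  if (length(keep) == 0L) stop_arg("no archetype passed the distinctness test")
  arch <- rowsum(sc[labels %in% keep, , drop = FALSE],
                 droplevels(labels[labels %in% keep])) /
    as.vector(table(droplevels(labels[labels %in% keep])))
  vals <- resemblance_matrix(scores, arch, space$axis_variance)
  trait_set(vals, "SYNDROME",
            trait_ids = paste0("SYN_", keep),
            provenance = data.frame(group = keep, p_distinct = pvals[keep]),
            seed = seed)
}
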