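#' Quasi-landmark mesh configurations
#'
#' A `mesh_config` holds `N` shapes in vertex correspondence as an
#' `N x L x 3` coordinate array together with the bilateral `mirror_map`, a
#' permutation pairing every vertex with its mirror-image counterpart
#' (midline vertices are paired with themselves).  The x axis is the lateral
#' axis: reflection negates x.
#'
#' @param coords numeric array `N x L x 3`.
#' @param mirror_map integer permutation of `1:L`; must be an involution.
#' @param vertex_ids optional character vertex labels.
#' @return an object of class `mesh_config`.
#' @export
mesh_config <- function(coords, mirror_map = NULL, vertex_ids = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop_arg("mesh coordinates must be finite")
  L <- dim(coords)[2]
  if (!is.null(mirror_map)) {
    mirror_map <- as.integer(mirror_map)
    if (length(mirror_map) != L || !identical(sort(mirror_map), seq_len(L)) ||
        !identical(mirror_map[mirror_map], seq_len(L)))
      stop_arg("`mirror_map` must be an involutory permutation of 1:L")
  }
  structure(list(coords = coords,
                 mirror_map = mirror_map,
                 vertex_ids = vertex_ids %||% sprintf("v%04d", seq_len(L))),
            class = "mesh_config")
}

#' @export
print.mesh_config <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("mesh_config: %d shape(s), %d vertices, 3 coordinates\n", d[1], d[2]))
  invisible(x)
}

n_shapes <- function(m) dim(m$coords)[1]
n_vertices <- function(m) dim(m$coords)[2]

#' Synthetic bilaterally symmetric face template
#'
#' Builds a half-ellipsoid grid standing in for a dense facial quasi-landmark
#' template: `n_polar` rows from forehead to chin crossed with `n_lateral`
#' (odd) columns from ear to ear, so the central column is the facial
#' midline.  The template carries a 24-landmark sparse subset (the first 5 of
#' which are nasal landmarks) and a "nose" vertex patch, mimicking the
#' face/segment dichotomy of dense facial mapping.  Units are millimetres.
#'
#' @param n_polar number of vertex rows (vertical direction).
#' @param n_lateral number of vertex columns; must be odd so that a midline
#'   column exists.  The default grid has `30 * 21 = 630` vertices.
#' @param semi_axes ellipsoid semi-axes (lateral, vertical, depth) in mm.
#' @return a list of class `face_template` with elements `mesh`
#'   (a 1-shape [mesh_config]), `landmarks` (24 named vertex indices),
#'   `nasal_landmarks` (5 named vertex indices), and `nose_patch`
#'   (vertex indices of the nasal segment).
#' @export
face_template <- function(n_polar = 30L, n_lateral = 21L,
                          semi_axes = c(65, 90, 55)) {
  n_polar <- as.integer(n_polar); n_lateral <- as.integer(n_lateral)
  if (n_polar < 4L || n_lateral < 5L) stop_arg("template grid too small")
  if (n_lateral %% 2L == 0L) stop_arg("`n_lateral` must be odd (midline column)")
  theta <- seq(0.18 * pi, 0.85 * pi, length.out = n_polar)   # polar, top->chin
  phi <- seq(-0.45 * pi, 0.45 * pi, length.out = n_lateral)  # lateral, left->right
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  L <- n_polar * n_lateral
  coords <- matrix(0, L, 3L)
  idx <- function(i, j) (j - 1L) * n_polar + i
  for (j in seq_len(n_lateral)) for (i in seq_len(n_polar)) {
    v <- idx(i, j)
    coords[v, ] <- c(a * sin(theta[i]) * sin(phi[j]),
                     b * cos(theta[i]),
                     cc * sin(theta[i]) * cos(phi[j]))
  }
  # mirror: column j pairs with column n_lateral + 1 - j (x -> -x)
  mirror <- integer(L)
  for (j in seq_len(n_lateral)) for (i in seq_len(n_polar)) {
    mirror[idx(i, j)] <- idx(i, n_lateral + 1L - j)
  }
  mid <- (n_lateral + 1L) %/% 2L                   # midline column index
  right <- function(f) mid + max(1L, round(f * (n_lateral - mid)))  # lateral offset
  row_at <- function(f) max(1L, min(n_polar, round(f * n_polar)))
  # nasal landmarks first; landmarks sit on the right half incl. the midline,
  # the convention for symmetrized faces
  lm <- c(
    nasion        = idx(row_at(0.38), mid),
    pronasale     = idx(row_at(0.55), mid),
    subnasale     = idx(row_at(0.62), mid),
    alare_r       = idx(row_at(0.55), right(0.12)),
    alar_crest_r  = idx(row_at(0.60), right(0.10)),
    glabella      = idx(row_at(0.30), mid),
    forehead      = idx(row_at(0.15), mid),
    labiale_sup   = idx(row_at(0.70), mid),
    stomion       = idx(row_at(0.74), mid),
    labiale_inf   = idx(row_at(0.78), mid),
    sublabiale    = idx(row_at(0.84), mid),
    pogonion      = idx(row_at(0.92), mid),
    gnathion      = idx(row_at(0.98), mid),
    endocanthion_r = idx(row_at(0.40), right(0.18)),
    exocanthion_r  = idx(row_at(0.40), right(0.45)),
    palpebrale_sup_r = idx(row_at(0.36), right(0.30)),
    palpebrale_inf_r = idx(row_at(0.44), right(0.30)),
    supraorbital_r = idx(row_at(0.28), right(0.33)),
    zygion_r      = idx(row_at(0.50), right(0.75)),
    tragion_r     = idx(row_at(0.45), right(0.95)),
    cheilion_r    = idx(row_at(0.74), right(0.25)),
    cheek_r       = idx(row_at(0.62), right(0.45)),
    gonion_r      = idx(row_at(0.82), right(0.60)),
    mid_mandible_r = idx(row_at(0.90), right(0.30))
  )
  # coarse grids can collapse nominal positions onto one vertex: move
  # collisions to the nearest unused right-half vertex (deterministically)
  rh <- as.vector(outer(seq_len(n_polar), mid:n_lateral, idx))
  if (length(rh) < length(lm)) stop_arg("template grid too coarse for 24 landmarks")
  grid_rc <- cbind(((rh - 1L) %% n_polar) + 1L, ((rh - 1L) %/% n_polar) + 1L)
  used <- logical(length(rh))
  for (q in seq_along(lm)) {
    slot <- match(lm[q], rh)
    if (!is.na(slot) && !used[slot]) { used[slot] <- TRUE; next }
    rc <- c(((lm[q] - 1L) %% n_polar) + 1L, ((lm[q] - 1L) %/% n_polar) + 1L)
    d2 <- (grid_rc[, 1] - rc[1])^2 + (grid_rc[, 2] - rc[2])^2
    d2[used] <- Inf
    pick <- which.min(d2)
    used[pick] <- TRUE
    lm[q] <- rh[pick]
  }
  # nose patch: block of rows/columns around the nasal landmarks
  rows <- row_at(0.36):row_at(0.66)
  cols <- max(1L, mid - (right(0.14) - mid)):right(0.14)
  nose <- as.vector(outer(rows, cols, idx))
  structure(list(
    mesh = mesh_config(array(coords, dim = c(1L, L, 3L)), mirror_map = mirror),
    landmarks = lm,
    nasal_landmarks = lm[1:5],
    nose_patch = sort(nose),
    grid = c(n_polar = n_polar, n_lateral = n_lateral)
  ), class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat(sprintf("face_template: %d vertices (%d x %d grid), %d landmarks, nose patch of %d vertices\n",
              n_vertices(x$mesh), x$grid[1], x$grid[2],
              length(x$landmarks), length(x$nose_patch)))
  invisible(x)
}

#' Orthonormal latent shape basis
#'
#' Draws `k` random directions in vertex space and orthonormalizes them; the
#' columns span the latent shape space along which genetic, covariate and
#' noise effects displace the template.  With `symmetric = TRUE` (default)
#' every direction is bilaterally symmetric, so planted effects survive
#' shape symmetrization.
#'
#' @param template a [face_template] (or a 1-shape [mesh_config] with a
#'   mirror map).
#' @param k number of basis directions.
#' @param symmetric make each direction mirror-symmetric before
#'   orthonormalization.
#' @param seed RNG seed.
#' @return a `3L x k` matrix with orthonormal columns.
#' @export
make_shape_basis <- function(template, k, symmetric = TRUE, seed = NULL) {
  mesh <- if (inherits(template, "face_template")) template$mesh else template
  L <- n_vertices(mesh)
  if (k < 1L || k > 3L * L) stop_arg("`k` must be in 1..3L")
  with_seed(seed, {
    B <- matrix(rnorm(3L * L * k), 3L * L, k)
    if (symmetric) {
      if (is.null(mesh$mirror_map)) stop_arg("template has no mirror map")
      B <- (B + reflect_flat(B, mesh$mirror_map)) / 2
    }
    qr.Q(qr(B))[, seq_len(k), drop = FALSE]
  })
}

# Apply the mirror operation to flattened shape vectors (columns of B are
# length-3L shape directions): permute vertices and negate x.
reflect_flat <- function(B, mirror_map) {
  L <- length(mirror_map)
  perm <- rep((mirror_map - 1L) * 3L, each = 3L) + rep(1:3, times = L)
  out <- B[perm, , drop = FALSE]
  xrows <- seq(1L, 3L * L, by = 3L)
  out[xrows, ] <- -out[xrows, ]
  out
}
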