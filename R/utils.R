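# shared small helpers; internal only

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_scalar_in <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_arg(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  invisible(x)
}

# Flatten an N x L x 3 coordinate array to N x 3L (vertex-major: the three
# coordinates of vertex v occupy columns 3(v-1)+1 .. 3v).
flatten_coords <- function(coords) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n <- dim(coords)[1]; L <- dim(coords)[2]
  out <- matrix(aperm(coords, c(1L, 3L, 2L)), nrow = n, ncol = 3L * L)
  out
}

# Inverse of flatten_coords().
unflatten_coords <- function(mat, L) {
  n <- nrow(mat)
  stopifnot(ncol(mat) == 3L * L)
  aperm(array(mat, dim = c(n, 3L, L)), c(1L, 3L, 2L))
}

centroid_size <- function(x) {
  # x: L x 3 single configuration
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2L, ctr)^2))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}
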