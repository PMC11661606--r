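# SIMPLS partial least squares (de Jong 1993), regression mode.
#
# Internal core used by covariate adjustment and the variance-explained
# measure.  Works for any predictor count >= 1; with ncomp equal to the
# rank of X the fitted values coincide with the ordinary least-squares fit,
# which the tests use as the oracle.
#
# Returns centred fitted values plus the column means needed to assemble
# predictions on the original scale.
simpls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n, ncomp >= 1)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  S <- crossprod(Xc, Yc)
  Tm <- matrix(0, n, ncomp)
  Q <- matrix(0, ncol(Y), ncomp)
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
    t_a <- Xc %*% r
    nt <- sqrt(sum(t_a^2))
    if (nt < .Machine$double.eps) { ncomp <- a - 1L; break }
    t_a <- t_a / nt; r <- r / nt
    p_a <- crossprod(Xc, t_a)
    q_a <- crossprod(Yc, t_a)
    v <- p_a
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_a)
    }
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps) { ncomp <- a - 1L; break }
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    Tm[, a] <- t_a; Q[, a] <- q_a; R[, a] <- r; V[, a] <- v
  }
  if (ncomp < 1L) stop_arg("PLS found no usable component")
  keep <- seq_len(ncomp)
  fitted_c <- Tm[, keep, drop = FALSE] %*% t(Q[, keep, drop = FALSE])
  list(fitted = sweep(fitted_c, 2L, my, `+`), ncomp = ncomp,
       scores = Tm[, keep, drop = FALSE], x_mean = mx, y_mean = my)
}
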