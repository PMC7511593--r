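# Central finite-difference derivatives. Steps are relative to the parameter
# magnitude (floored at 1) so scale differences between loadings, variances
# and intercepts do not degrade accuracy.

fd_steps <- function(x, rel_step) pmax(1, abs(x)) * rel_step

fd_gradient <- function(f, x, rel_step = 1e-6) {
  h <- fd_steps(x, rel_step)
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h[j]
    xm[j] <- xm[j] - h[j]
    (f(xp) - f(xm)) / (2 * h[j])
  }, numeric(1))
}

# Jacobian of a vector-valued f (rows = components of f(x), cols = params).
fd_jacobian <- function(f, x, rel_step = 1e-6) {
  h <- fd_steps(x, rel_step)
  cols <- lapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h[j]
    xm[j] <- xm[j] - h[j]
    (f(xp) - f(xm)) / (2 * h[j])
  })
  do.call(cbind, cols)
}

# Numerical Hessian from forward second differences: p(p+1)/2 + p + 1
# evaluations instead of ~2p^2, at O(h) truncation error. Used where the
# objective is expensive and 3-4 significant digits suffice.
fd_hessian_forward <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- fd_steps(x, rel_step)
  f0 <- f(x)
  fj <- vapply(seq_len(p), function(j) {
    xp <- x; xp[j] <- xp[j] + h[j]; f(xp)
  }, numeric(1))
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      xjk <- x
      xjk[j] <- xjk[j] + h[j]
      xjk[k] <- xjk[k] + h[k]
      H[j, k] <- H[k, j] <- (f(xjk) - fj[j] - fj[k] + f0) / (h[j] * h[k])
    }
  }
  H
}

# Symmetric numerical Hessian from central second differences.
fd_hessian <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- fd_steps(x, rel_step)
  f0 <- f(x)
  H <- matrix(NA_real_, p, p)
  fp <- numeric(p); fm <- numeric(p)
  for (j in seq_len(p)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h[j]
    xm[j] <- xm[j] - h[j]
    fp[j] <- f(xp); fm[j] <- f(xm)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  if (p > 1) {
    for (j in seq_len(p - 1)) {
      for (k in seq((j + 1), p)) {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(j, k)] <- xpp[c(j, k)] + h[c(j, k)]
        xpm[j] <- xpm[j] + h[j]; xpm[k] <- xpm[k] - h[k]
        xmp[j] <- xmp[j] - h[j]; xmp[k] <- xmp[k] + h[k]
        xmm[c(j, k)] <- xmm[c(j, k)] - h[c(j, k)]
        H[j, k] <- H[k, j] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[j] * h[k])
      }
    }
  }
  H
}
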