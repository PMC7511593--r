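# Independent numerical oracles used by the tests. These deliberately avoid
# the package's computational shortcuts (low-rank Woodbury algebra, adaptive
# node placement): densities are evaluated through full 14x14 covariance
# factorizations and the moderator is integrated out on a dense deterministic
# grid.

# log N(x; mu, Sigma) for the rows of X, via a full Cholesky factorization
oracle_dmvnorm_log <- function(X, mu, sigma) {
  ch <- chol(sigma)
  d <- ncol(X)
  u <- backsolve(ch, t(X) - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(u^2))
}

# Conditional moments of the 14 indicators given the latent moderator value z,
# rebuilt from the structural equations themselves.
oracle_conditional_moments <- function(par, z) {
  lam_x <- c(1, par[["lambda_x2"]], par[["lambda_x3"]])
  lam_m <- c(1, par[["lambda_m2"]], par[["lambda_m3"]], par[["lambda_m4"]])
  lam_z <- c(1, par[["lambda_z2"]], par[["lambda_z3"]])
  lam_y <- c(1, par[["lambda_y2"]], par[["lambda_y3"]], par[["lambda_y4"]])
  tau <- par[paste0("tau_", modmedsem:::IND_COLS)]
  theta <- par[paste0("theta_", modmedsem:::IND_COLS)]
  a <- par[["a"]]; b1 <- par[["b1"]]; b2 <- par[["b2"]]
  b3 <- par[["b3"]]; cc <- par[["c"]]
  phx <- par[["phi_x"]]; phz <- par[["phi_z"]]; phxz <- par[["phi_xz"]]
  psm <- par[["psi_m"]]; psy <- par[["psi_y"]]

  gam <- phxz / phz
  v <- phx - phxz^2 / phz
  beta <- b1 + b3 * z
  # eta = (X, M, Y) = A (X*, zeta_M, zeta_Y) + mean, X* ~ N(gam z, v)
  A <- matrix(c(1, 0, 0,
                a, 1, 0,
                cc + beta * a, beta, 1), 3, 3, byrow = TRUE)
  mu_eta <- c(gam * z, a * gam * z, (cc + beta * a) * gam * z + b2 * z)
  psi_z <- A %*% diag(c(v, psm, psy)) %*% t(A)
  L <- matrix(0, 14, 3)
  L[1:3, 1] <- lam_x
  L[4:7, 2] <- lam_m
  L[11:14, 3] <- lam_y
  d_vec <- c(rep(0, 7), lam_z, rep(0, 4))
  mu <- unname(tau) + drop(L %*% mu_eta) + d_vec * z
  sigma <- L %*% psi_z %*% t(L) + diag(unname(theta))
  list(mean = mu, cov = sigma)
}

# Marginal log-likelihood via dense-grid trapezoid integration over z.
oracle_lms_loglik <- function(par, data, z_lim = 10, dz = 0.01) {
  X <- as.matrix(data[, modmedsem:::IND_COLS])
  grid <- seq(-z_lim, z_lim, by = dz)
  phz <- par[["phi_z"]]
  logf <- vapply(grid, function(z) {
    cm <- oracle_conditional_moments(par, z)
    oracle_dmvnorm_log(X, cm$mean, cm$cov) + dnorm(z, 0, sqrt(phz), log = TRUE)
  }, numeric(nrow(X)))
  if (nrow(X) == 1) logf <- matrix(logf, nrow = 1)
  apply(logf, 1, function(lr) {
    m <- max(lr)
    m + log(sum(exp(lr - m)) * dz) # trapezoid; endpoints are ~0 anyway
  })
}
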