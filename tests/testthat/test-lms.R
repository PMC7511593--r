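test_that("Gauss-Hermite rule is exact and normalized", {
  gh <- gauss_hermite(16)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(gh$nodes, -rev(gh$nodes), tolerance = 1e-12)
  # integrates polynomials against exp(-t^2): E t^2 = 1/2, E t^4 = 3/4
  expect_equal(sum(gh$weights * gh$nodes^2) / sqrt(pi), 0.5, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^4) / sqrt(pi), 0.75, tolerance = 1e-10)
})

test_that("quadrature log-likelihood matches an independent integration oracle", {
  spec <- hi_spec(b3 = 0.2)
  dat <- tiny_data()
  par <- population_lms_params(spec)
  ll_quad <- lms_loglik(par, dat, K = 16)
  ll_grid <- sum(oracle_lms_loglik(par, dat))
  expect_equal(ll_quad, ll_grid, tolerance = 1e-3)
  # the oracle itself is converged: halving the step barely moves it
  ll_grid2 <- sum(oracle_lms_loglik(par, dat, dz = 0.005))
  expect_lt(abs(ll_grid - ll_grid2), 1e-8)
  # cross-check one case against adaptive deterministic integration (QUADPACK)
  phz <- par[["phi_z"]]
  x1 <- dat[1, ]
  f <- function(z) {
    vapply(z, function(zi) {
      cm <- oracle_conditional_moments(par, zi)
      exp(oracle_dmvnorm_log(as.matrix(x1), cm$mean, cm$cov)) *
        dnorm(zi, 0, sqrt(phz))
    }, numeric(1))
  }
  lik1 <- stats::integrate(f, -10, 10, rel.tol = 1e-10)$value
  expect_equal(lms_loglik(par, dat, K = 16, casewise = TRUE)[1], log(lik1),
               tolerance = 1e-6)
  # correlated moderator and nonzero interaction still match
  spec2 <- make_population_spec(design_cell(n = 5, b3 = 0.4, cor_xz = 0.3))
  dat2 <- generate_dataset(spec2, seed = 8)
  par2 <- population_lms_params(spec2)
  expect_equal(lms_loglik(par2, dat2, K = 16),
               sum(oracle_lms_loglik(par2, dat2)), tolerance = 1e-3)
})

test_that("quadrature is self-convergent in K and invariant to case order", {
  dat <- generate_dataset(hi_spec(b3 = 0.2), n = 200, seed = 9)
  par <- population_lms_params(hi_spec(b3 = 0.2))
  l16 <- lms_loglik(par, dat, K = 16)
  l32 <- lms_loglik(par, dat, K = 32)
  l64 <- lms_loglik(par, dat, K = 64)
  expect_lt(abs(l16 - l64), 1e-6)
  expect_lte(abs(l32 - l64), abs(l16 - l64) + 1e-9)
  perm <- dat[rev(seq_len(nrow(dat))), ]
  expect_equal(lms_loglik(par, perm, K = 16), l16, tolerance = 1e-9)
})

test_that("with b3 fixed at zero LMS coincides with the linear SEM", {
  dat <- generate_dataset(hi_spec(b3 = 0), n = 300, seed = 10)
  f_lin <- ml_fit(modmedsem:::linear_sem_model(dat), dat)
  # identical likelihood value at the same parameter point
  pp <- setNames(numeric(48), lms_param_names())
  pp[names(f_lin$estimates)] <- f_lin$estimates
  pp["b3"] <- 0
  expect_equal(lms_loglik(pp, dat, K = 5), f_lin$loglik, tolerance = 1e-8)
  # and the constrained LMS fit lands on the same solution
  f_lms0 <- fit_lms(dat, fix_b3 = 0, se = "none")
  expect_true(f_lms0$converged)
  shared <- names(f_lin$estimates)
  expect_lt(max(abs(f_lms0$estimates[shared] - f_lin$estimates[shared])), 1e-4)
  expect_equal(f_lms0$loglik, f_lin$loglik, tolerance = 1e-6)
})

test_that("LMS recovers the interaction and its robust errors behave", {
  dat <- generate_dataset(hi_spec(b3 = 0.2), n = 2000, seed = 11)
  fit <- fit_lms(dat)
  expect_true(fit$converged)
  expect_true(fit$proper_solution)
  expect_true(fit$extra$se_ok)
  expect_lt(abs(fit$estimates[["b3"]] - 0.2), 3 * fit$se[["b3"]])
  # information equality under correct specification: robust ~ inverse-Hessian
  se_h <- sqrt(diag(fit$extra$vcov_hessian))
  expect_gt(fit$se[["b3"]] / se_h[["b3"]], 0.85)
  expect_lt(fit$se[["b3"]] / se_h[["b3"]], 1.15)
  # robust_se() reproduces the stored standard errors
  expect_equal(robust_se(fit, dat), fit$se, tolerance = 1e-8)
  # duplicating every case halves the sampling variance exactly
  dup <- dplyr::bind_rows(dat[1:250, ], dat[1:250, ])
  f1 <- fit_lms(dat[1:250, ])
  f2 <- fit_lms(dup)
  expect_equal(f2$se[["b3"]] / f1$se[["b3"]], 1 / sqrt(2), tolerance = 0.03)
})

test_that("likelihood-ratio comparison is calibrated under the null", {
  lr0 <- lr_test(structure(list(loglik = -100), class = "mmm_fit"),
                 structure(list(loglik = -100), class = "mmm_fit"))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  expect_warning(
    lr_test(structure(list(loglik = -100), class = "mmm_fit"),
            structure(list(loglik = -101), class = "mmm_fit")),
    "lower log-likelihood"
  )
  # null distribution of the statistic over replications is ~ chi-square(1)
  reps <- 60
  spec0 <- hi_spec(b3 = 0)
  stats <- vapply(seq_len(reps), function(i) {
    d <- generate_dataset(spec0, n = 200, seed = 2000 + i)
    f0 <- fit_lms(d, fix_b3 = 0, se = "none")
    f1 <- fit_lms(d, se = "none")
    lr_test(f0, f1)$statistic
  }, numeric(1))
  expect_gt(mean(stats), 0.5)  # E chi2(1) = 1
  expect_lt(mean(stats), 1.8)
  ks <- suppressWarnings(stats::ks.test(stats, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.001)
  # high power at a strong interaction
  spec4 <- hi_spec(b3 = 0.4, n = 200)
  rej <- vapply(1:20, function(i) {
    d <- generate_dataset(spec4, seed = 3000 + i)
    f0 <- fit_lms(d, fix_b3 = 0, se = "none")
    f1 <- fit_lms(d, se = "none")
    lr_test(f0, f1)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("Johnson-Neyman band matches its analytic crossovers", {
  # deterministic fit stub with known covariance
  fit <- modmedsem:::new_mmm_fit(
    method = "lms",
    estimates = c(b1 = 0.5, b3 = 0.25),
    vcov = matrix(c(0.04, 0.002, 0.002, 0.01), 2, 2,
                  dimnames = list(c("b1", "b3"), c("b1", "b3")))
  )
  band <- johnson_neyman(fit, z_grid = seq(-6, 6, length.out = 4001))
  expect_equal(band$slope[band$z == 0], 0.5)
  cross <- attr(band, "crossings")
  # grid scan agrees with the quadratic-formula roots inside the grid range
  flips <- which(diff(band$significant) != 0)
  grid_cross <- (band$z[flips] + band$z[flips + 1]) / 2
  in_range <- cross >= min(band$z) & cross <= max(band$z)
  expect_equal(sum(in_range), length(grid_cross))
  expect_lt(max(abs(cross[in_range] - grid_cross)), 0.01)
  # zero interaction: constant band equal to b1 +/- 1.96 se(b1)
  fit0 <- modmedsem:::new_mmm_fit(
    method = "lms", estimates = c(b1 = 0.5, b3 = 0),
    vcov = matrix(c(0.04, 0, 0, 0), 2, 2,
                  dimnames = list(c("b1", "b3"), c("b1", "b3")))
  )
  band0 <- johnson_neyman(fit0, z_grid = c(-2, 0, 2))
  expect_equal(band0$slope, rep(0.5, 3))
  expect_equal(band0$ci_lower, rep(0.5 - qnorm(0.975) * 0.2, 3))
  pl <- autoplot(band)
  expect_s3_class(pl, "ggplot")
})
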