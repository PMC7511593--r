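test_that("population spec carries the study parameterization", {
  spec <- make_population_spec(design_cell(n = 500, b3 = 0.2,
                                           reliability = "high",
                                           distribution_type = 1, cor_xz = 0))
  expect_equal(spec$measurement$M$loadings, c(1, 0.81, 0.53, 0.66))
  expect_equal(spec$measurement$M$loadings[3], 0.53)
  expect_equal(spec$measurement$X$loadings, c(1, 0.65, 0.72))
  expect_equal(spec$measurement$Z$loadings, c(1, 0.83, 0.79))
  expect_equal(spec$measurement$Y$loadings, c(1, 0.68, 0.75, 0.83))
  expect_true(all(unlist(lapply(spec$measurement, `[[`, "intercepts")) == 0.5))
  expect_true(all(unlist(lapply(spec$measurement, `[[`, "error_variances")) == 0.36))
  expect_equal(spec$structural[c("a", "b1", "b2", "b3", "c")],
               list(a = 0.75, b1 = 0.56, b2 = 0.48, b3 = 0.2, c = 0.3))

  low <- make_population_spec(design_cell(n = 100, b3 = 0, reliability = "low"))
  expect_true(all(unlist(lapply(low$measurement, `[[`, "error_variances")) == 1.5))
  expect_equal(low$structural$resid_var_m, 0.36)
  expect_equal(low$structural$resid_var_y, 0.36)

  cor <- make_population_spec(design_cell(n = 200, b3 = 0.2, cor_xz = 0.3))
  expect_equal(cor$structural$cov_xz, 0.3)

  # non-normal errors apply to M and Z blocks only
  t3 <- make_population_spec(design_cell(n = 200, distribution_type = 3))
  expect_equal(t3$measurement$X$error_distribution, "normal")
  expect_equal(t3$measurement$Y$error_distribution, "normal")
  expect_equal(t3$measurement$M$error_distribution, "symm_moderate_kurtosis")
  expect_equal(t3$measurement$Z$error_distribution, "symm_moderate_kurtosis")

  expect_error(design_cell(distribution_type = 7), "distribution_type")
})

test_that("error distributions have the stated moments", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  kurt <- function(x) mean((x - mean(x))^4) / sd(x)^4
  set.seed(1)
  n <- 4e5
  e1 <- sample_error(1, 0.36, n)
  expect_equal(var(e1), 0.36, tolerance = 0.01)
  expect_equal(mean(e1), 0, tolerance = 0.01)

  e2 <- sample_error(2, 0.36, n)
  expect_equal(mean(e2), 0, tolerance = 0.005) # centred uniform
  expect_equal(var(e2), 1 / 12, tolerance = 0.01)
  e2r <- sample_error(2, 0.36, n, rescale_nonnormal = TRUE)
  expect_equal(var(e2r), 0.36, tolerance = 0.01)

  e3 <- sample_error(3, 0.36, n)
  expect_equal(var(e3), 0.36, tolerance = 0.05)
  expect_lt(abs(skew(e3)), 0.25)
  expect_gt(kurt(e3), 4) # heavier than normal

  e4 <- sample_error(4, 0.36, n)
  expect_gt(kurt(e4), kurt(e3)) # type 4 is the heavier construction

  e5 <- sample_error(5, 0.36, 8e5)
  expect_equal(mean(e5), 0, tolerance = 0.01)
  expect_equal(var(e5), 2, tolerance = 0.05)        # natural chi-square(1) variance
  expect_equal(skew(e5), sqrt(8), tolerance = 0.25) # 2.83
  e5r <- sample_error(5, 0.36, n, rescale_nonnormal = TRUE)
  expect_equal(var(e5r), 0.36, tolerance = 0.02)

  expect_error(sample_error("nonsense", 1, 10))
})

test_that("generated data converge to the closed-form moment oracle", {
  spec <- hi_spec(b3 = 0.2)
  pm <- population_moments(spec)
  n <- 1e5
  dat <- generate_dataset(spec, n = n, seed = 123)
  X <- as.matrix(dat)
  # means within 5 standard errors
  se_mean <- sqrt(diag(pm$cov) / n)
  expect_true(all(abs(colMeans(X) - pm$mean) < 5 * se_mean))
  # covariances within 5 SEs (Gaussian-moment approximation of the SE)
  S <- cov(X)
  se_cov <- sqrt((outer(diag(pm$cov), diag(pm$cov)) + pm$cov^2) / n)
  expect_true(all(abs(S - pm$cov) < 5 * se_cov))
  # spot values: Var(M) propagates into the scaling indicator of M
  expect_equal(pm$cov["m1", "m1"], 0.9225 + 0.36)
  expect_equal(mean(dat$x1), 0.5, tolerance = 0.02)
})

test_that("population moments obey the stated algebra", {
  spec0 <- hi_spec(b3 = 0)
  pm0 <- population_moments(spec0)
  # Cov(m1, x1) = lambda_m1 lambda_x1 a Var(X)
  expect_equal(pm0$cov["m1", "x1"], 0.75)
  # with b3 = 0 and cor 0, M and Z blocks are uncorrelated
  expect_true(all(abs(pm0$cov[c("m1", "m2"), c("z1", "z2", "z3")]) < 1e-12))
  # Y-block variance from first principles (no interaction contribution)
  s <- spec0$structural
  var_m <- s$a^2 + s$resid_var_m
  var_y <- s$c^2 + s$b1^2 * var_m + s$b2^2 + 2 * s$c * s$b1 * s$a + s$resid_var_y
  expect_equal(pm0$cov["y1", "y1"], var_y + 0.36, tolerance = 1e-12)
  # symmetric positive definite
  expect_lt(max(abs(pm0$cov - t(pm0$cov))), 1e-12)
  expect_gt(min(eigen(pm0$cov, symmetric = TRUE, only.values = TRUE)$values), 0)
  # latent interaction variance identity (Var(M) Var(Z) + Cov^2)
  pm3 <- population_moments(make_population_spec(
    design_cell(n = 100, b3 = 0.4, cor_xz = 0.3)))
  expect_gt(min(eigen(pm3$cov, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(population_moments(make_population_spec(
    design_cell(n = 100, distribution_type = 5))), "normal")
})

test_that("reliability manipulation matches its closed-form alphas", {
  hi <- hi_spec()
  lo <- make_population_spec(design_cell(n = 500, b3 = 0.2, reliability = "low"))
  # closed form from the stated loadings and error variances, e.g. for X:
  # (3/2) (1 - (sum lambda^2 Var(X) + 3 theta) / ((sum lambda)^2 Var(X) + 3 theta))
  alpha_closed <- function(lam, var_lat, theta) {
    k <- length(lam)
    (k / (k - 1)) *
      (1 - (sum(lam^2) * var_lat + k * theta) /
             (sum(lam)^2 * var_lat + k * theta))
  }
  expect_equal(population_alpha(hi, "X"),
               alpha_closed(c(1, 0.65, 0.72), 1, 0.36), tolerance = 1e-12)
  expect_equal(population_alpha(hi, "X"), 0.823366, tolerance = 1e-6)
  expect_equal(population_alpha(hi, "M"),
               alpha_closed(c(1, 0.81, 0.53, 0.66), 0.9225, 0.36),
               tolerance = 1e-12)
  expect_equal(population_alpha(hi, "M"), 0.8367156, tolerance = 1e-6)
  expect_equal(population_alpha(hi, "Z"), 0.8593601, tolerance = 1e-6)
  expect_equal(population_alpha(lo, "X"),
               alpha_closed(c(1, 0.65, 0.72), 1, 1.5), tolerance = 1e-12)
  # monotone in the error variance, every block
  for (b in c("X", "M", "Z", "Y")) {
    expect_lt(population_alpha(lo, b), population_alpha(hi, b))
  }
  # sample alpha approaches the population alpha
  dat <- generate_dataset(hi, n = 5e4, seed = 9)
  expect_equal(cronbach_alpha(dat, "X"), population_alpha(hi, "X"),
               tolerance = 0.01)
  # identical items have alpha 1
  const <- tibble::tibble(x1 = rnorm(50))
  const$x2 <- const$x1; const$x3 <- const$x1
  expect_equal(cronbach_alpha(const, "X"), 1)
})

test_that("generation is deterministic given a seed and seeds are substreamed", {
  spec <- hi_spec()
  d1 <- generate_dataset(spec, n = 50, seed = 7)
  d2 <- generate_dataset(spec, n = 50, seed = 7)
  expect_identical(d1, d2)
  d3 <- generate_dataset(spec, n = 50, seed = 8)
  expect_false(isTRUE(all.equal(d1, d3)))
  # substream seeds differ across cells and replications, are < 2^31
  s <- outer(1:20, 1:50, function(c, r) {
    mapply(function(ci, ri) substream_seed(1, ci, ri), c, r)
  })
  expect_equal(length(unique(as.vector(s))), 1000L)
  expect_true(all(s > 0 & s < 2^31))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(generate_dataset(spec, n = 10, seed = 3))
  expect_identical(before, .Random.seed)
})

test_that("dataset and spec serialization round-trip", {
  spec <- make_population_spec(design_cell(n = 30, b3 = 0.4, reliability = "low",
                                           distribution_type = 5, cor_xz = 0.3))
  dat <- generate_dataset(spec, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_indicator_csv(dat, f)
  expect_equal(as.data.frame(read_indicator_csv(f)), as.data.frame(dat),
               tolerance = 1e-12)
  g <- withr::local_tempfile(fileext = ".yaml")
  write_population_spec(spec, g)
  spec2 <- read_population_spec(g)
  expect_equal(spec2$structural, spec$structural)
  expect_equal(spec2$measurement$M$loadings, spec$measurement$M$loadings)
  expect_equal(spec2$measurement$Z$error_distribution, "skewed_chisq1")
})
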