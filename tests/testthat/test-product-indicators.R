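test_that("indicators are matched by descending loading with index tie-breaks", {
  p <- match_indicators(c(1, 0.81, 0.53, 0.66), c(1, 0.83, 0.79))
  expect_equal(p$m, c("m1", "m2", "m4")) # m3 (0.53) left unmatched
  expect_equal(p$z, c("z1", "z2", "z3"))
  expect_equal(p$product, c("mz1", "mz2", "mz3"))

  tie <- match_indicators(c(1, 1, 1), c(1, 1, 1))
  expect_equal(tie$m, c("m1", "m2", "m3"))
  expect_equal(tie$z, c("z1", "z2", "z3"))

  single <- match_indicators(1, 1)
  expect_equal(nrow(single), 1L)
})

test_that("product indicators are element-wise products of (centred) columns", {
  dat <- generate_dataset(hi_spec(), n = 50, seed = 1)
  dat$m1 <- 2; dat$z1 <- 3
  pairing <- match_indicators(c(1, 0.81, 0.53, 0.66), c(1, 0.83, 0.79))
  raw <- build_product_indicators(dat, pairing, center = FALSE)
  expect_true(all(raw$mz1 == 6))
  cen <- build_product_indicators(dat, pairing, center = TRUE)
  expect_equal(mean(cen$mz2),
               cov(dat$m2, dat$z2) * (nrow(dat) - 1) / nrow(dat))
  # population data, cor 0, b3 = 0: centred products have mean near zero
  big <- generate_dataset(hi_spec(b3 = 0), n = 1e5, seed = 2)
  cen_big <- build_product_indicators(big, pairing, center = TRUE)
  expect_lt(abs(mean(cen_big$mz1)), 0.01)
})

test_that("the nonlinear constraints reproduce their arithmetic", {
  con <- cpi_constraints(
    lambda_m = c(1, 0.81), lambda_z = c(1, 0.83),
    theta_m = c(0.36, 0.36), theta_z = c(0.36, 0.36),
    a = 0.75, phi_x = 1, phi_z = 1, phi_xz = 0, psi_m = 0.36
  )
  expect_equal(con$lambda_mz[1], 1)
  expect_equal(con$lambda_mz[2], 0.81 * 0.83)
  # Var(d_mz1) = 1 * 0.9225 * 0.36 + 1 * 1 * 0.36 + 0.36^2 = 0.8217
  expect_equal(con$theta_mz[1], 0.8217)
  # Var(MZ) = 0.9225 * 1 + 0 under cor 0
  expect_equal(con$var_mz, 0.9225)
  expect_equal(con$e_mz, 0)
  con3 <- cpi_constraints(1, 1, 0.36, 0.36, a = 0.75, phi_x = 1, phi_z = 1,
                          phi_xz = 0.3, psi_m = 0.36)
  expect_equal(con3$e_mz, 0.225)
  expect_equal(con3$var_mz, 0.9225 + 0.225^2)
  expect_error(
    cpi_constraints(1, 1, -0.1, 0.36, a = 0.75, phi_x = 1, phi_z = 1,
                    phi_xz = 0, psi_m = 0.36),
    "non-negative"
  )
})

test_that("CPI model moments equal the population oracle at the true parameters", {
  spec <- hi_spec(b3 = 0.2)
  dat <- generate_dataset(spec, n = 100, seed = 3)
  pairing <- match_indicators(spec$measurement$M$loadings,
                              spec$measurement$Z$loadings)
  aug <- build_product_indicators(dat, pairing)
  model <- modmedsem:::pi_model(aug, pairing, "cpi")
  truth <- population_lms_params(spec)
  th <- model$free
  th[names(truth)[names(truth) %in% names(th)]] <-
    truth[names(truth)[names(truth) %in% names(th)]]
  im <- implied_moments(model, th)
  pm <- population_moments(spec)
  expect_lt(max(abs(im$cov[IND <- modmedsem:::IND_COLS, IND] - pm$cov)), 1e-10)
  expect_lt(max(abs(im$mean[IND] - pm$mean)), 1e-10)
})

test_that("fitted CPI satisfies the constraints algebraically; UPI frees exactly 8", {
  dat <- generate_dataset(hi_spec(b3 = 0.2, cor_xz = 0.3), n = 400, seed = 4)
  pairing <- match_indicators(c(1, 0.81, 0.53, 0.66), c(1, 0.83, 0.79))
  fc <- fit_cpi(dat, pairing = pairing)
  fu <- fit_upi(dat, pairing = pairing)
  expect_true(fc$converged)
  expect_true(fu$converged)
  expect_equal(length(fu$estimates) - length(fc$estimates), 8L)

  th <- fc$estimates
  mats <- modmedsem:::pi_model(
    build_product_indicators(dat, pairing), pairing, "cpi"
  )$build(th)
  con <- cpi_constraints(
    lambda_m = c(1, th[["lambda_m2"]])[c(1, 2)],
    lambda_z = c(1, th[["lambda_z2"]])[c(1, 2)],
    theta_m = th[c("theta_m1", "theta_m2")],
    theta_z = th[c("theta_z1", "theta_z2")],
    a = th[["a"]], phi_x = th[["phi_x"]], phi_z = th[["phi_z"]],
    phi_xz = th[["phi_xz"]], psi_m = th[["psi_m"]]
  )
  # loading and error-variance constraints hold at the optimum
  expect_equal(unname(mats$Lambda["mz1", "MZ"]), unname(con$lambda_mz[1]),
               tolerance = 1e-12)
  expect_equal(unname(mats$Lambda["mz2", "MZ"]), unname(con$lambda_mz[2]),
               tolerance = 1e-12)
  expect_equal(unname(mats$theta[15:16]), unname(con$theta_mz),
               tolerance = 1e-12)
  # latent-mean and variance constraints
  expect_equal(unname(mats$nu[["MZ"]]), th[["a"]] * th[["phi_xz"]],
               tolerance = 1e-12)
  expect_equal(unname(mats$Psi["MZ", "MZ"]), unname(con$var_mz),
               tolerance = 1e-12)
  # UPI keeps only the latent-mean constraint
  mats_u <- modmedsem:::pi_model(
    build_product_indicators(dat, pairing), pairing, "upi"
  )$build(fu$estimates)
  expect_equal(unname(mats_u$nu[["MZ"]]),
               fu$estimates[["a"]] * fu$estimates[["phi_xz"]], tolerance = 1e-12)
  expect_equal(unname(mats_u$Psi["MZ", "MZ"]), fu$estimates[["var_mz"]])
})

test_that("both product-indicator fits give sensible interaction estimates", {
  dat <- generate_dataset(hi_spec(b3 = 0.2), n = 500, seed = 5)
  fc <- fit_cpi(dat)
  fu <- fit_upi(dat)
  expect_true(fc$proper_solution)
  expect_true(fu$proper_solution)
  expect_lt(abs(fc$estimates[["b3"]] - 0.2), 0.15)
  expect_lt(abs(fu$estimates[["b3"]] - 0.2), 0.2)
  expect_equal(fc$effects$term, c("index", "ind_m1sd", "ind_0", "ind_p1sd"))
})
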