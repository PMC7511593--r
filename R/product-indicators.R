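# Product-indicator SEM. Products of matched mediator and moderator
# indicators measure the latent interaction; the constrained variant (CPI)
# ties every product-indicator parameter to the base measurement and
# structural parameters, the unconstrained variant (UPI) keeps only the
# latent-mean constraint E(MZ) = a Cov(X, Z).

#' Match mediator and moderator indicators by factor loading
#'
#' Sorts each factor's indicators by loading in descending order and pairs
#' them rank to rank until the shorter list is exhausted; leftover indicators
#' stay unmatched (they keep loading on their own factor only). Ties are
#' broken by original indicator order.
#'
#' @param loadings_m,loadings_z Loading vectors of the mediator and moderator
#'   indicators.
#' @param names_m,names_z Indicator column names (defaults `m1..`, `z1..`).
#' @return A tibble with columns `m`, `z` and `product` (the product-indicator
#'   name `mz1..`), one row per pair, ordered by decreasing loading rank.
#' @export
#' @examples
#' match_indicators(c(1, 0.81, 0.53, 0.66), c(1, 0.83, 0.79))
match_indicators <- function(loadings_m, loadings_z,
                             names_m = paste0("m", seq_along(loadings_m)),
                             names_z = paste0("z", seq_along(loadings_z))) {
  stopifnot(length(loadings_m) >= 1, length(loadings_z) >= 1)
  ord_m <- order(-loadings_m, seq_along(loadings_m))
  ord_z <- order(-loadings_z, seq_along(loadings_z))
  k <- min(length(loadings_m), length(loadings_z))
  tibble::tibble(
    m = names_m[ord_m[seq_len(k)]],
    z = names_z[ord_z[seq_len(k)]],
    product = paste0("mz", seq_len(k))
  )
}

#' Append product indicators to an indicator dataset
#'
#' Forms element-wise products of the paired (optionally mean-centred)
#' mediator and moderator indicator columns.
#'
#' @param data Indicator dataset.
#' @param pairing A [match_indicators()] result.
#' @param center Mean-centre the paired columns before multiplying? (Default
#'   `TRUE`, the metric in which the latent-mean constraint is applied.)
#' @return `data` with the product columns appended.
#' @export
build_product_indicators <- function(data, pairing, center = TRUE) {
  stopifnot(all(c(pairing$m, pairing$z) %in% names(data)))
  out <- data
  for (j in seq_len(nrow(pairing))) {
    mcol <- data[[pairing$m[j]]]
    zcol <- data[[pairing$z[j]]]
    if (center) {
      mcol <- mcol - mean(mcol)
      zcol <- zcol - mean(zcol)
    }
    out[[pairing$product[j]]] <- mcol * zcol
  }
  out
}

#' Nonlinear constraints of the constrained product-indicator model
#'
#' For each matched pair, the product indicator's loading, error variance, and
#' the latent interaction's variance and mean are deterministic functions of
#' the base parameters:
#' `lambda_mz = lambda_m * lambda_z`;
#' `Var(d_mz) = lambda_m^2 Var(M) Var(d_z) + lambda_z^2 Var(Z) Var(d_m) + Var(d_m) Var(d_z)`
#' with `Var(M) = a^2 Var(X) + Var(zeta_M)`;
#' `Var(MZ) = Var(M) Var(Z) + (a Cov(X, Z))^2`; and `E(MZ) = a Cov(X, Z)`.
#'
#' @param lambda_m,lambda_z Loadings of the paired indicators (vectors, one
#'   entry per pair).
#' @param theta_m,theta_z Error variances of the paired indicators.
#' @param a Path from X to M.
#' @param phi_x,phi_z,phi_xz Latent (co)variances of X and Z.
#' @param psi_m Structural residual variance of M.
#' @return A list with `lambda_mz`, `theta_mz` (vectors) and scalars `var_mz`,
#'   `e_mz`.
#' @export
#' @examples
#' cpi_constraints(1, 1, 0.36, 0.36, a = 0.75, phi_x = 1, phi_z = 1,
#'                 phi_xz = 0, psi_m = 0.36)
cpi_constraints <- function(lambda_m, lambda_z, theta_m, theta_z,
                            a, phi_x, phi_z, phi_xz, psi_m) {
  if (any(c(theta_m, theta_z, phi_x, phi_z, psi_m) < 0)) {
    stop("variance inputs to the product-indicator constraints must be non-negative")
  }
  var_m <- a^2 * phi_x + psi_m
  list(
    lambda_mz = lambda_m * lambda_z,
    theta_mz = lambda_m^2 * var_m * theta_z + lambda_z^2 * phi_z * theta_m +
      theta_m * theta_z,
    var_mz = var_m * phi_z + (a * phi_xz)^2,
    e_mz = a * phi_xz
  )
}

# Index of each paired indicator within its block (e.g. "m4" -> 4).
indicator_index <- function(cols) as.integer(sub("^[a-z]+", "", cols))

# Build the CPI or UPI sem_model for a dataset augmented with product columns.
pi_model <- function(data_aug, pairing, approach = c("cpi", "upi")) {
  approach <- match.arg(approach)
  k <- nrow(pairing)
  prod_cols <- pairing$product
  observed <- c(IND_COLS, prod_cols)
  latent <- c("X", "M", "Z", "MZ", "Y")

  lam_names <- c(paste0("lambda_x", 2:3), paste0("lambda_m", 2:4),
                 paste0("lambda_z", 2:3), paste0("lambda_y", 2:4))
  tau_names <- paste0("tau_", IND_COLS)
  theta_names <- paste0("theta_", IND_COLS)
  base_names <- c(lam_names, tau_names, theta_names,
                  "a", "b1", "b2", "b3", "c",
                  "phi_x", "phi_z", "phi_xz", "psi_m", "psi_y")

  X <- as.matrix(data_aug[, observed])
  col_mean <- colMeans(X)
  col_var <- apply(X, 2, var)
  start <- c(
    setNames(rep(1, length(lam_names)), lam_names),
    setNames(col_mean[IND_COLS], tau_names),
    setNames(col_var[IND_COLS] / 2, theta_names),
    a = 0, b1 = 0, b2 = 0, b3 = 0, c = 0,
    phi_x = unname(col_var["x1"] / 2), phi_z = unname(col_var["z1"] / 2),
    phi_xz = 0,
    psi_m = unname(col_var["m1"] / 2), psi_y = unname(col_var["y1"] / 2)
  )
  if (approach == "upi") {
    extra <- c(
      setNames(rep(1, k - 1), paste0("lambda_", prod_cols[-1])),
      setNames(col_var[prod_cols] / 2, paste0("theta_", prod_cols)),
      var_mz = unname(col_var[prod_cols[1]]),
      cov_mz_x = 0, cov_mz_z = 0
    )
    start <- c(start, extra)
  }

  m_idx <- indicator_index(pairing$m)
  z_idx <- indicator_index(pairing$z)

  build <- function(th) {
    lam <- list(
      X = c(1, th["lambda_x2"], th["lambda_x3"]),
      M = c(1, th["lambda_m2"], th["lambda_m3"], th["lambda_m4"]),
      Z = c(1, th["lambda_z2"], th["lambda_z3"]),
      Y = c(1, th["lambda_y2"], th["lambda_y3"], th["lambda_y4"])
    )
    lam_m_pair <- lam$M[m_idx]
    lam_z_pair <- lam$Z[z_idx]
    theta_m_pair <- th[paste0("theta_", pairing$m)]
    theta_z_pair <- th[paste0("theta_", pairing$z)]
    con <- cpi_constraints(
      lam_m_pair, lam_z_pair, pmax(theta_m_pair, 0), pmax(theta_z_pair, 0),
      a = th[["a"]], phi_x = max(th[["phi_x"]], 0), phi_z = max(th[["phi_z"]], 0),
      phi_xz = th[["phi_xz"]], psi_m = max(th[["psi_m"]], 0)
    )
    if (approach == "cpi") {
      lambda_mz <- con$lambda_mz
      theta_mz <- con$theta_mz
      var_mz <- con$var_mz
      cov_mz_x <- 0; cov_mz_z <- 0
    } else {
      lambda_mz <- c(1, unname(th[paste0("lambda_", prod_cols[-1])]))
      theta_mz <- unname(th[paste0("theta_", prod_cols)])
      var_mz <- th[["var_mz"]]
      cov_mz_x <- th[["cov_mz_x"]]; cov_mz_z <- th[["cov_mz_z"]]
    }
    p <- length(observed)
    Lambda <- matrix(0, p, 5, dimnames = list(observed, latent))
    for (b in names(BLOCK_COLS)) Lambda[BLOCK_COLS[[b]], b] <- lam[[b]]
    Lambda[prod_cols, "MZ"] <- lambda_mz
    lat <- structural_latent_moments(
      a = th[["a"]], b1 = th[["b1"]], b2 = th[["b2"]], b3 = th[["b3"]],
      c = th[["c"]],
      phi_x = th[["phi_x"]], phi_z = th[["phi_z"]], phi_xz = th[["phi_xz"]],
      psi_m = th[["psi_m"]], psi_y = th[["psi_y"]],
      var_mz = var_mz, cov_mz_x = cov_mz_x, cov_mz_z = cov_mz_z,
      e_mz = con$e_mz
    )
    list(
      tau = c(unname(th[tau_names]), rep(0, k)), # product intercepts fixed 0
      Lambda = Lambda,
      theta = c(unname(th[theta_names]), theta_mz),
      nu = lat$nu,
      Psi = lat$P
    )
  }
  sem_model(observed, latent, start, build)
}

# Rank indicators within a block by their summed covariance with the other
# indicators of the block (monotone in the loading under a one-factor model);
# used to derive a data-driven pairing when none is supplied.
estimate_block_loading_order <- function(data, block) {
  S <- cov(as.matrix(data[, BLOCK_COLS[[block]]]))
  rowSums(S) - diag(S)
}

default_pairing <- function(data, pairing) {
  if (!is.null(pairing)) return(pairing)
  match_indicators(
    estimate_block_loading_order(data, "M"),
    estimate_block_loading_order(data, "Z")
  )
}

fit_pi <- function(data, approach, pairing = NULL, center = TRUE,
                   se = "none", control = list()) {
  pairing <- default_pairing(data, pairing)
  data_c <- data
  mz_cols <- c(BLOCK_COLS$M, BLOCK_COLS$Z)
  if (center) {
    data_c[mz_cols] <- lapply(data_c[mz_cols], function(v) v - mean(v))
  }
  aug <- build_product_indicators(data_c, pairing, center = FALSE)
  model <- pi_model(aug, pairing, approach)
  fit <- ml_fit(model, aug, se = se, control = control)
  fit$method <- approach
  est <- fit$estimates
  if (all(is.finite(est[c("a", "b1", "b3", "phi_z")]))) {
    sd_z <- sqrt(max(est[["phi_z"]], 0))
    fit$effects <- conditional_effects_tbl(est[["a"]], est[["b1"]], est[["b3"]], sd_z)
    fit$extra$moderator_sd <- sd_z
  }
  fit$extra$pairing <- pairing
  fit
}

#' Fit the moderated mediation model by product-indicator SEM
#'
#' `fit_cpi()` fits the constrained product-indicator model: product-indicator
#' loadings, product error variances and the latent interaction's variance and
#' mean are all tied to the base parameters through [cpi_constraints()].
#' `fit_upi()` fits the unconstrained variant, which keeps only the
#' latent-mean constraint `E(MZ) = a Cov(X, Z)`; product loadings (bar the
#' first, fixed to 1 for scale), product error variances, `Var(MZ)` and the
#' covariances of MZ with X and Z are freely estimated. Both centre the
#' mediator and moderator indicators before forming products and identify each
#' factor by fixing its first loading to 1.
#'
#' @param data Indicator dataset (14 columns).
#' @param pairing A [match_indicators()] result; by default indicators are
#'   matched by a data-driven loading ranking. Simulation drivers pass the
#'   population pairing.
#' @param center Mean-centre mediator and moderator indicators (default TRUE).
#' @param se `"none"` or `"hessian"` (see [ml_fit()]).
#' @param control Passed to [ml_fit()].
#' @return An `mmm_fit` with an `effects` tibble; conditional indirect effects
#'   are evaluated at z = -1, 0, +1 estimated latent SD `sqrt(phi_z)`.
#' @export
fit_cpi <- function(data, pairing = NULL, center = TRUE, se = "none",
                    control = list()) {
  fit_pi(data, "cpi", pairing = pairing, center = center, se = se, control = control)
}

#' @rdname fit_cpi
#' @export
fit_upi <- function(data, pairing = NULL, center = TRUE, se = "none",
                    control = list()) {
  fit_pi(data, "upi", pairing = pairing, center = center, se = se, control = control)
}
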