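# Maximum-likelihood covariance/mean-structure engine. A model is a mapping
# from a free-parameter vector to LISREL-type reduced-form matrices; arbitrary
# functional constraints (e.g. the product-indicator constraints) live inside
# that mapping, so the optimizer only ever sees the free parameters.

#' Define a covariance/mean-structure model
#'
#' A model maps a named free-parameter vector to the reduced-form matrices of
#' a linear latent-variable model: indicator intercepts `tau` (length p),
#' loading matrix `Lambda` (p x q), indicator error variances `theta` (length
#' p), latent means `nu` (length q) and latent covariance `Psi` (q x q).
#' Nonlinear parameter constraints are expressed inside `build`, which must be
#' total on the free-parameter space.
#'
#' @param observed Character vector of observed-variable names (order fixes
#'   the row order of `Lambda`).
#' @param latent Character vector of latent-variable names.
#' @param free Named numeric vector of free parameters with start values.
#' @param build `function(theta)` returning
#'   `list(tau, Lambda, theta, nu, Psi)`.
#' @return An object of class `sem_model`.
#' @export
sem_model <- function(observed, latent, free, build) {
  stopifnot(is.character(observed), is.character(latent),
            is.numeric(free), !is.null(names(free)), is.function(build))
  structure(
    list(observed = observed, latent = latent, free = free, build = build),
    class = "sem_model"
  )
}

#' Model-implied moments of the observed variables
#'
#' Applies the model's constraint mapping and assembles the implied mean
#' vector `tau + Lambda nu` and covariance matrix
#' `Lambda Psi Lambda' + diag(theta)`.
#'
#' @param model A [sem_model()].
#' @param free_params Named numeric vector of free parameters (defaults to the
#'   model's start values).
#' @return A list with `mean` and `cov`.
#' @export
implied_moments <- function(model, free_params = model$free) {
  stopifnot(all(is.finite(free_params)))
  m <- model$build(free_params)
  sigma <- m$Lambda %*% m$Psi %*% t(m$Lambda) + diag(m$theta, nrow = length(m$theta))
  if (max(abs(sigma - t(sigma))) > 1e-10) {
    stop("internal error: implied covariance is not symmetric")
  }
  mu <- drop(m$tau + m$Lambda %*% m$nu)
  names(mu) <- model$observed
  dimnames(sigma) <- list(model$observed, model$observed)
  list(mean = mu, cov = sigma)
}

# Normal-theory ML discrepancy with mean structure, given sample moments.
# Returns a large penalty when the implied covariance is not PD so the
# optimizer retreats rather than erroring.
ml_discrepancy <- function(model, xbar, S, logdet_s) {
  p <- length(xbar)
  function(th) {
    m <- model$build(th)
    sigma <- m$Lambda %*% m$Psi %*% t(m$Lambda) + diag(m$theta, nrow = p)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    d <- xbar - drop(m$tau + m$Lambda %*% m$nu)
    val <- logdet + sum(inv * S) - logdet_s - p + drop(d %*% inv %*% d)
    if (!is.finite(val)) 1e10 else val
  }
}

#' Fit a structural-equation model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p + (xbar - mu)' Sigma^-1 (xbar - mu)`
#' over the model's free parameters with a quasi-Newton optimizer
#' ([stats::nlminb()], numerical gradients). Non-convergence is reported in
#' the returned object rather than raised, so simulation completion rates can
#' be computed. A solution is flagged *proper* when the optimizer converged,
#' every estimated variance (indicator error variances and latent variances)
#' is non-negative, and the implied covariance at the optimum is positive
#' definite.
#'
#' @param model A [sem_model()].
#' @param data Data frame containing the model's observed columns.
#' @param se `"none"` (default) or `"hessian"` for observed-information
#'   standard errors of the free parameters.
#' @param control List: `iter_max` (default 1000), `grad_tol` (default 1e-4,
#'   used only to report the gradient norm check).
#' @return An object of class `mmm_fit`.
#' @export
ml_fit <- function(model, data, se = c("none", "hessian"), control = list()) {
  se <- match.arg(se)
  ctl <- utils::modifyList(list(iter_max = 1000L, grad_tol = 1e-4), control)
  X <- as.matrix(data[, model$observed])
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more cases than observed variables")
  if (any(apply(X, 2, var) == 0)) stop("zero-variance observed column")
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar)) / n # ML covariance (denominator n)
  ch_s <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_s)) stop("singular sample covariance matrix")
  logdet_s <- 2 * sum(log(diag(ch_s)))
  obj <- ml_discrepancy(model, xbar, S, logdet_s)

  res <- tryCatch(
    nlminb(model$free, obj,
           control = list(iter.max = ctl$iter_max, eval.max = 20L * ctl$iter_max)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(new_mmm_fit(method = "sem", estimates = model$free * NA_real_,
                       loglik = NA_real_, converged = FALSE,
                       proper_solution = FALSE, n_obs = n, model = model))
  }
  est <- setNames(res$par, names(model$free))
  f_hat <- res$objective
  grad <- tryCatch(fd_gradient(obj, est), error = function(e) rep(NA_real_, length(est)))
  grad_norm <- max(abs(grad))
  # nlminb can report "false convergence" at a genuine optimum once the
  # objective is flat to finite-difference precision; a flat gradient of the
  # (scale-free) discrepancy is accepted as convergence
  converged <- is.finite(f_hat) && f_hat < 1e9 &&
    (res$convergence == 0 || (is.finite(grad_norm) && grad_norm < 1e-3))
  loglik <- -n / 2 * (p * log(2 * pi) + f_hat + logdet_s + p)

  mats <- model$build(est)
  sigma_hat <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + diag(mats$theta, nrow = p)
  sigma_pd <- !is.null(tryCatch(chol(sigma_hat), error = function(e) NULL))
  proper <- isTRUE(converged) &&
    all(mats$theta >= 0) && all(diag(mats$Psi) >= -1e-10) && sigma_pd

  vcov <- NULL; se_vec <- NULL
  if (se == "hessian" && converged) {
    # observed information of the full loglik: Hessian of n/2 * F
    H <- tryCatch(fd_hessian(obj, est) * n / 2, error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov)) {
        dimnames(vcov) <- list(names(est), names(est))
        se_vec <- sqrt(pmax(diag(vcov), 0))
      }
    }
  }

  new_mmm_fit(
    method = "sem", estimates = est, se = se_vec, vcov = vcov,
    loglik = loglik, converged = converged, proper_solution = proper,
    n_obs = n, discrepancy = f_hat, grad_norm = grad_norm, model = model
  )
}

# Shared fit container used by every estimator.
new_mmm_fit <- function(method, estimates, se = NULL, vcov = NULL,
                        ci_lower = NULL, ci_upper = NULL,
                        loglik = NA_real_, converged = FALSE,
                        proper_solution = FALSE, n_obs = NA_integer_,
                        effects = NULL, ...) {
  structure(
    list(
      method = method, estimates = estimates, se = se, vcov = vcov,
      ci_lower = ci_lower, ci_upper = ci_upper, loglik = loglik,
      converged = converged, proper_solution = proper_solution,
      n_obs = n_obs, effects = effects, extra = list(...)
    ),
    class = "mmm_fit"
  )
}

#' @export
print.mmm_fit <- function(x, ...) {
  cat(sprintf("<mmm_fit: %s>  n = %s, loglik = %s, converged = %s, proper = %s\n",
              x$method, x$n_obs,
              if (is.na(x$loglik)) "NA" else formatC(x$loglik, format = "f", digits = 2),
              x$converged, x$proper_solution))
  est <- x$estimates
  show <- intersect(c("a", "b1", "b2", "b3", "c"), names(est))
  if (length(show)) {
    cat("  paths: ", paste(sprintf("%s = %.3f", show, est[show]), collapse = ", "), "\n")
  }
  if (!is.null(x$effects)) {
    cat("  effects: ",
        paste(sprintf("%s = %.3f", x$effects$term, x$effects$estimate), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Latent means/covariance of (X, M, Z, MZ, Y) implied by structural
# coefficients plus the exogenous moments of (X, Z, MZ). Shared by the
# product-indicator model builders.
structural_latent_moments <- function(a, b1, b2, b3, c,
                                      phi_x, phi_z, phi_xz,
                                      psi_m, psi_y,
                                      var_mz, cov_mz_x, cov_mz_z, e_mz) {
  lat <- c("X", "M", "Z", "MZ", "Y")
  nu <- setNames(c(0, 0, 0, e_mz, b3 * e_mz), lat)
  P <- matrix(0, 5, 5, dimnames = list(lat, lat))
  P["X", "X"] <- phi_x
  P["Z", "Z"] <- phi_z
  P["X", "Z"] <- P["Z", "X"] <- phi_xz
  P["MZ", "MZ"] <- var_mz
  P["X", "MZ"] <- P["MZ", "X"] <- cov_mz_x
  P["Z", "MZ"] <- P["MZ", "Z"] <- cov_mz_z
  # M = a X + zeta_M
  P["M", "M"] <- a^2 * phi_x + psi_m
  P["M", "X"] <- P["X", "M"] <- a * phi_x
  P["M", "Z"] <- P["Z", "M"] <- a * phi_xz
  P["M", "MZ"] <- P["MZ", "M"] <- a * cov_mz_x
  # Y = c X + b1 M + b2 Z + b3 MZ + zeta_Y
  bvec <- c(X = c, M = b1, Z = b2, MZ = b3)
  pred <- c("X", "M", "Z", "MZ")
  for (v in pred) P["Y", v] <- P[v, "Y"] <- sum(bvec * P[pred, v])
  P["Y", "Y"] <- drop(bvec %*% P[pred, pred] %*% bvec) + psi_y
  list(nu = nu, P = P)
}
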