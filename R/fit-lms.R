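# Latent moderated structural equations: the latent interaction enters as a
# conditionally linear effect, the moderator is integrated out by adaptive
# Gauss-Hermite quadrature, and inference uses robust sandwich standard
# errors.

#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for `integral exp(-t^2) f(t) dt` via the Golub-Welsch
#' eigendecomposition of the Jacobi matrix. Weights sum to `sqrt(pi)` (i.e.
#' to 1 after normalization by the Gaussian kernel's mass).
#'
#' @param K Number of quadrature points (>= 2).
#' @return List with `nodes` and `weights`, ascending in the nodes.
#' @export
gauss_hermite <- function(K) {
  stopifnot(K >= 2)
  off <- sqrt(seq_len(K - 1) / 2)
  J <- matrix(0, K, K)
  J[cbind(seq_len(K - 1), seq_len(K - 1) + 1L)] <- off
  J[cbind(seq_len(K - 1) + 1L, seq_len(K - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(
    nodes = e$values[ord],
    weights = sqrt(pi) * (e$vectors[1, ord])^2
  )
}

#' Canonical parameter names of the LMS model
#'
#' The fixed ordering of the 48 parameters of the full measurement-plus-
#' structural model: free loadings, indicator intercepts, indicator error
#' variances, structural paths `a, b1, b2, b3, c`, exogenous (co)variances
#' `phi_x, phi_z, phi_xz` and structural residual variances `psi_m, psi_y`.
#'
#' @return Character vector of length 48.
#' @export
lms_param_names <- function() {
  c(
    paste0("lambda_x", 2:3), paste0("lambda_m", 2:4),
    paste0("lambda_z", 2:3), paste0("lambda_y", 2:4),
    paste0("tau_", IND_COLS), paste0("theta_", IND_COLS),
    "a", "b1", "b2", "b3", "c",
    "phi_x", "phi_z", "phi_xz", "psi_m", "psi_y"
  )
}

#' Map a population spec to the canonical LMS parameter vector
#'
#' @param spec A [make_population_spec()] result.
#' @return Named numeric vector in [lms_param_names()] order.
#' @export
population_lms_params <- function(spec) {
  m <- spec$measurement; s <- spec$structural
  setNames(c(
    m$X$loadings[-1], m$M$loadings[-1], m$Z$loadings[-1], m$Y$loadings[-1],
    unlist(lapply(m, `[[`, "intercepts"), use.names = FALSE),
    unlist(lapply(m, `[[`, "error_variances"), use.names = FALSE),
    s$a, s$b1, s$b2, s$b3, s$c,
    s$var_x, s$var_z, s$cov_xz, s$resid_var_m, s$resid_var_y
  ), lms_param_names())
}

# log(omega_k) + t_k^2, the node constants of the adapted quadrature rule.
gh_log_weights <- function(gh) log(gh$weights) + gh$nodes^2

#' Marginal log-likelihood of the LMS model
#'
#' Evaluates the mixture representation of the marginal likelihood: for each
#' quadrature node `z_k` the model is linear-Gaussian conditional on the
#' latent moderator, so the 14 indicators are jointly normal with
#' node-specific moments, and the per-case likelihood is the weighted node
#' sum. Nodes are recentred per case on the moderator's posterior under the
#' `b3 = 0` linearisation of `params`, which makes the rule exact (any K)
#' when `b3 = 0` and rapidly convergent otherwise.
#'
#' @param params Named parameter vector covering [lms_param_names()].
#' @param data Indicator dataset.
#' @param K Quadrature order (default 16).
#' @param casewise Return the per-case log-likelihood vector instead of the
#'   total?
#' @return Total log-likelihood (scalar) or a length-n vector. Infeasible
#'   parameter points (non-positive variances) give `-1e12`.
#' @export
lms_loglik <- function(params, data, K = 16, casewise = FALSE) {
  par <- params[lms_param_names()]
  if (anyNA(par)) stop("params must cover all canonical LMS parameter names")
  X <- as.matrix(data[, IND_COLS])
  gh <- gauss_hermite(K)
  if (casewise) {
    drop(cpp_lms_loglik_casewise(unname(par), X, gh$nodes, gh_log_weights(gh)))
  } else {
    cpp_lms_loglik_total(unname(par), X, gh$nodes, gh_log_weights(gh))
  }
}

# Linear SEM for the 14 indicators (no latent interaction): the b3 = 0
# sub-model, used both on its own and to produce LMS start values.
linear_sem_model <- function(data) {
  nm <- setdiff(lms_param_names(), "b3")
  X <- as.matrix(data[, IND_COLS])
  col_mean <- colMeans(X); col_var <- apply(X, 2, var)
  start <- setNames(numeric(length(nm)), nm)
  start[paste0("lambda_x", 2:3)] <- 1
  start[paste0("lambda_m", 2:4)] <- 1
  start[paste0("lambda_z", 2:3)] <- 1
  start[paste0("lambda_y", 2:4)] <- 1
  start[paste0("tau_", IND_COLS)] <- col_mean
  start[paste0("theta_", IND_COLS)] <- col_var / 2
  start[c("a", "b1", "b2", "c", "phi_xz")] <- 0
  start["phi_x"] <- col_var[["x1"]] / 2
  start["phi_z"] <- col_var[["z1"]] / 2
  start["psi_m"] <- col_var[["m1"]] / 2
  start["psi_y"] <- col_var[["y1"]] / 2

  # fixed template and positional parameter map (hot path: this builder runs
  # once per objective evaluation)
  Lambda0 <- matrix(0, 14, 4, dimnames = list(IND_COLS, c("X", "M", "Z", "Y")))
  lam_pos <- cbind(
    row = c(1:3, 4:7, 8:10, 11:14),
    col = rep(1:4, times = c(3, 4, 3, 4))
  )
  build <- function(th) {
    lam_vals <- c(1, th[1L:2L], 1, th[3L:5L], 1, th[6L:7L], 1, th[8L:10L])
    Lambda <- Lambda0
    Lambda[lam_pos] <- lam_vals
    a <- th[[39L]]; b1 <- th[[40L]]; b2 <- th[[41L]]; cc <- th[[42L]]
    phx <- th[[43L]]; phz <- th[[44L]]; phxz <- th[[45L]]
    psm <- th[[46L]]; psy <- th[[47L]]
    var_m <- a^2 * phx + psm
    cyx <- cc * phx + b1 * a * phx + b2 * phxz
    cym <- cc * a * phx + b1 * var_m + b2 * a * phxz
    cyz <- cc * phxz + b1 * a * phxz + b2 * phz
    Psi <- matrix(c(
      phx,      a * phx, phxz,     cyx,
      a * phx,  var_m,   a * phxz, cym,
      phxz,     a * phxz, phz,     cyz,
      cyx,      cym,     cyz,      cc * cyx + b1 * cym + b2 * cyz + psy
    ), 4, 4)
    list(
      tau = unname(th[11L:24L]),
      Lambda = Lambda,
      theta = unname(th[25L:38L]),
      nu = c(0, 0, 0, 0),
      Psi = Psi
    )
  }
  sem_model(IND_COLS, c("X", "M", "Z", "Y"), start, build)
}

lms_proper <- function(par) {
  theta <- par[paste0("theta_", IND_COLS)]
  all(theta >= 0) && par[["phi_x"]] > 0 && par[["phi_z"]] > 0 &&
    (par[["phi_x"]] * par[["phi_z"]] - par[["phi_xz"]]^2) > 0 &&
    par[["psi_m"]] >= 0 && par[["psi_y"]] >= 0
}

#' Fit the moderated mediation model by latent moderated structural equations
#'
#' Maximizes the marginal likelihood of [lms_loglik()] with a quasi-Newton
#' optimizer, starting from the maximum-likelihood solution of the linear
#' (no-interaction) structural equation model. Non-convergence is recorded in
#' the returned object, never raised. Robust (sandwich) standard errors
#' `A^-1 B A^-1` are computed from the numerical observed information `A` and
#' the outer product of per-case scores `B`; standard errors of the moderated
#' mediation index and the conditional indirect effects (evaluated at
#' z = -1, 0, +1 estimated latent SD `sqrt(phi_z)`) follow by the delta
#' method.
#'
#' @param data Indicator dataset (14 columns).
#' @param K Quadrature order (default 16).
#' @param fix_b3 Fix the interaction coefficient at this value instead of
#'   estimating it (use `fix_b3 = 0` for the no-interaction null model whose
#'   log-likelihood feeds [lr_test()]).
#' @param se `"robust"` (default) or `"none"`.
#' @param start Optional named start vector over [lms_param_names()].
#' @param control List: `iter_max` (default 500).
#' @return An `mmm_fit` with estimates, robust standard errors, the robust
#'   covariance matrix of the free parameters, 95% Wald intervals, and an
#'   `effects` tibble.
#' @export
#' @examples
#' \donttest{
#' spec <- make_population_spec(design_cell(n = 300, b3 = 0.4))
#' fit <- fit_lms(generate_dataset(spec, seed = 3))
#' glance(fit)
#' }
fit_lms <- function(data, K = 16, fix_b3 = NULL, se = c("robust", "none"),
                    start = NULL, control = list()) {
  se <- match.arg(se)
  ctl <- utils::modifyList(list(iter_max = 500L), control)
  X <- as.matrix(data[, IND_COLS])
  n <- nrow(X)
  gh <- gauss_hermite(K)
  lw <- gh_log_weights(gh)
  nm <- lms_param_names()

  if (is.null(start)) {
    fit0 <- tryCatch(ml_fit(linear_sem_model(data), data), error = function(e) NULL)
    start <- setNames(numeric(48), nm)
    if (!is.null(fit0) && fit0$converged) {
      start[names(fit0$estimates)] <- fit0$estimates
      # keep the start inside the feasible region
      start[paste0("theta_", IND_COLS)] <-
        pmax(start[paste0("theta_", IND_COLS)], 1e-3)
      start[c("phi_x", "phi_z", "psi_m", "psi_y")] <-
        pmax(start[c("phi_x", "phi_z", "psi_m", "psi_y")], 1e-3)
    } else {
      start[names(linear_sem_model(data)$free)] <- linear_sem_model(data)$free
    }
    start["b3"] <- 0
  } else {
    start <- start[nm]
    if (anyNA(start)) stop("start must cover all canonical LMS parameter names")
  }

  free_names <- if (is.null(fix_b3)) nm else setdiff(nm, "b3")
  assemble <- function(th_free) {
    full <- setNames(numeric(48), nm)
    full[free_names] <- th_free
    if (!is.null(fix_b3)) full["b3"] <- fix_b3
    full
  }
  negll <- function(th_free) {
    -cpp_lms_loglik_total(unname(assemble(th_free)), X, gh$nodes, lw)
  }

  # two-phase search: the bulk of the optimization runs on a coarser adaptive
  # rule (identical to ~1e-5 on this model), then a short polish at full K
  res <- NULL
  if (K > 8) {
    gh_c <- gauss_hermite(8)
    lw_c <- gh_log_weights(gh_c)
    negll_c <- function(th_free) {
      -cpp_lms_loglik_total(unname(assemble(th_free)), X, gh_c$nodes, lw_c)
    }
    res0 <- tryCatch(
      nlminb(start[free_names], negll_c,
             control = list(iter.max = ctl$iter_max,
                            eval.max = 20L * ctl$iter_max, rel.tol = 1e-8)),
      error = function(e) NULL
    )
    if (!is.null(res0)) start[free_names] <- res0$par
  }
  res <- tryCatch(
    nlminb(start[free_names], negll,
           control = list(iter.max = ctl$iter_max,
                          eval.max = 20L * ctl$iter_max, rel.tol = 1e-8)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(new_mmm_fit(method = "lms", estimates = setNames(rep(NA_real_, 48), nm),
                       loglik = NA_real_, converged = FALSE,
                       proper_solution = FALSE, n_obs = n, K = K, fix_b3 = fix_b3))
  }
  est_free <- setNames(res$par, free_names)
  full <- assemble(est_free)
  feasible <- is.finite(res$objective) && res$objective < 1e11
  converged <- feasible && res$convergence == 0
  if (feasible && !converged) {
    # at large n the finite-difference noise of the gradient exceeds nlminb's
    # internal tolerances and it reports "false convergence" at the optimum;
    # accept the point when the gradient is flat relative to the loglik scale
    g <- tryCatch(fd_gradient(negll, res$par), error = function(e) NA_real_)
    rel_g <- max(abs(g)) / max(abs(res$objective), 1)
    converged <- is.finite(rel_g) && rel_g < 1e-6
  }
  proper <- isTRUE(converged) && lms_proper(full)

  fit <- new_mmm_fit(
    method = "lms", estimates = full, loglik = -res$objective,
    converged = converged, proper_solution = proper, n_obs = n,
    K = K, fix_b3 = fix_b3, free_names = free_names,
    data_cols = IND_COLS
  )
  sd_z <- sqrt(max(full[["phi_z"]], 0))
  fit$effects <- conditional_effects_tbl(full[["a"]], full[["b1"]],
                                         full[["b3"]], sd_z)
  fit$extra$moderator_sd <- sd_z

  if (se == "robust" && converged) {
    fit <- add_lms_robust_se(fit, X, gh, lw)
  }
  fit
}

# Sandwich covariance + delta-method effect SEs, attached to the fit.
add_lms_robust_se <- function(fit, X, gh, lw) {
  nm <- lms_param_names()
  free_names <- fit$extra$free_names
  fix_b3 <- fit$extra$fix_b3
  est_free <- fit$estimates[free_names]
  assemble <- function(th_free) {
    full <- setNames(numeric(48), nm)
    full[free_names] <- th_free
    if (!is.null(fix_b3)) full["b3"] <- fix_b3
    full
  }
  negll <- function(th_free) {
    -cpp_lms_loglik_total(unname(assemble(th_free)), X, gh$nodes, lw)
  }
  casewise <- function(th_free) {
    drop(cpp_lms_loglik_casewise(unname(assemble(th_free)), X, gh$nodes, lw))
  }
  A <- tryCatch(fd_hessian_forward(negll, est_free, rel_step = 1e-4),
                error = function(e) NULL)
  scores <- tryCatch(fd_jacobian(casewise, est_free, rel_step = 1e-5),
                     error = function(e) NULL)
  if (is.null(A) || is.null(scores) || anyNA(A) || anyNA(scores)) {
    fit$extra$se_ok <- FALSE
    return(fit)
  }
  B <- crossprod(scores)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    fit$extra$se_ok <- FALSE
    return(fit)
  }
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(free_names, free_names)
  se_vec <- sqrt(pmax(diag(V), 0))
  if (any(!is.finite(se_vec)) || any(se_vec == 0 & free_names %in% c("a", "b1", "b3"))) {
    fit$extra$se_ok <- FALSE
  } else {
    fit$extra$se_ok <- TRUE
  }
  fit$se <- se_vec
  fit$vcov <- V
  fit$extra$vcov_hessian <- {
    Vh <- Ainv
    dimnames(Vh) <- list(free_names, free_names)
    Vh
  }
  fit$ci_lower <- fit$estimates[free_names] - qnorm(0.975) * se_vec
  fit$ci_upper <- fit$estimates[free_names] + qnorm(0.975) * se_vec

  # delta-method SEs of index and conditional indirect effects
  eff_fun <- function(th_free) {
    full <- assemble(th_free)
    sd_z <- sqrt(max(full[["phi_z"]], 0))
    conditional_effects_tbl(full[["a"]], full[["b1"]], full[["b3"]], sd_z)$estimate
  }
  Jac <- fd_jacobian(eff_fun, est_free)
  eff_se <- sqrt(pmax(diag(Jac %*% V %*% t(Jac)), 0))
  fit$effects$se <- eff_se
  fit$effects$ci_lower <- fit$effects$estimate - qnorm(0.975) * eff_se
  fit$effects$ci_upper <- fit$effects$estimate + qnorm(0.975) * eff_se
  fit
}

#' Robust sandwich standard errors for an LMS fit
#'
#' Recomputes the sandwich estimator `A^-1 B A^-1` at the fitted parameters,
#' with `A` the numerical Hessian of the total negative log-likelihood and `B`
#' the sum of outer products of per-case score vectors (central finite
#' differences).
#'
#' @param fit A converged [fit_lms()] result.
#' @param data The dataset the model was fitted to.
#' @return Named vector of robust standard errors over the free parameters.
#' @export
robust_se <- function(fit, data) {
  stopifnot(inherits(fit, "mmm_fit"), fit$method == "lms")
  if (!fit$converged) stop("robust_se() needs a converged fit")
  X <- as.matrix(data[, IND_COLS])
  gh <- gauss_hermite(fit$extra$K)
  fit2 <- add_lms_robust_se(fit, X, gh, gh_log_weights(gh))
  if (!isTRUE(fit2$extra$se_ok)) {
    stop("sandwich information matrix is singular; standard errors unavailable")
  }
  fit2$se
}

#' Log-likelihood ratio comparison of nested interaction models
#'
#' Compares the model without the latent interaction (Model 0, `b3` fixed at
#' zero) against the model with it (Model 1): `LR = -2 (l0 - l1)` referred to
#' chi-square with 1 df.
#'
#' @param fit_null Fit with `b3` fixed at 0 (e.g. `fit_lms(data, fix_b3 = 0)`
#'   or the linear-SEM [ml_fit()]).
#' @param fit_alt Fit with `b3` free.
#' @return Tibble with `statistic`, `df`, `p_value` and a `warning_flag` set
#'   when the alternative log-likelihood is below the null beyond tolerance
#'   (an optimizer-failure signal).
#' @export
lr_test <- function(fit_null, fit_alt) {
  stat <- -2 * (fit_null$loglik - fit_alt$loglik)
  warn <- is.finite(stat) && stat < -1e-4
  if (warn) {
    warning("alternative model has lower log-likelihood than the null; ",
            "optimizer may not have converged")
  }
  stat_c <- max(stat, 0)
  tibble::tibble(
    statistic = stat_c, df = 1L,
    p_value = pchisq(stat_c, df = 1, lower.tail = FALSE),
    warning_flag = warn
  )
}

#' Johnson-Neyman probing of the simple slope
#'
#' Computes the simple slope of the mediator on the outcome,
#' `b1 + b3 z`, across a grid of moderator values, with normal-theory
#' confidence bands from the fit's parameter covariance, and solves
#' analytically for the moderator values where the band crosses zero.
#'
#' @param fit An `mmm_fit` whose `vcov` covers `b1` and `b3` (LMS with robust
#'   standard errors, path analysis, or an [ml_fit()] with `se = "hessian"`).
#' @param z_grid Moderator values at which to evaluate the band.
#' @param level Confidence level (default 0.95).
#' @return A tibble of class `jn_band` with columns `z, slope, se, ci_lower,
#'   ci_upper, significant`; the analytic crossover points are in
#'   `attr(, "crossings")`.
#' @export
johnson_neyman <- function(fit, z_grid = seq(-3, 3, length.out = 201),
                           level = 0.95) {
  if (is.null(fit$vcov) || !all(c("b1", "b3") %in% rownames(fit$vcov))) {
    stop("fit must carry a covariance matrix for b1 and b3")
  }
  b1 <- fit$estimates[["b1"]]; b3 <- fit$estimates[["b3"]]
  v1 <- fit$vcov["b1", "b1"]; v3 <- fit$vcov["b3", "b3"]
  c13 <- fit$vcov["b1", "b3"]
  q <- qnorm(1 - (1 - level) / 2)
  slope <- b1 + b3 * z_grid
  se <- sqrt(pmax(v1 + z_grid^2 * v3 + 2 * z_grid * c13, 0))
  out <- tibble::tibble(
    z = z_grid, slope = slope, se = se,
    ci_lower = slope - q * se, ci_upper = slope + q * se
  )
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  # roots of (b1 + b3 z)^2 = q^2 (v1 + 2 c13 z + v3 z^2)
  qa <- b3^2 - q^2 * v3
  qb <- 2 * (b1 * b3 - q^2 * c13)
  qc <- b1^2 - q^2 * v1
  disc <- qb^2 - 4 * qa * qc
  crossings <- if (qa == 0) {
    if (qb != 0) -qc / qb else numeric(0)
  } else if (disc >= 0) {
    sort(c((-qb - sqrt(disc)) / (2 * qa), (-qb + sqrt(disc)) / (2 * qa)))
  } else {
    numeric(0)
  }
  attr(out, "crossings") <- crossings
  attr(out, "level") <- level
  class(out) <- c("jn_band", class(out))
  out
}
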