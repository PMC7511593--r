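# Composite-score path analysis: block means stand in for the latent
# variables, the interaction is the product of the (optionally mean-centred)
# mediator and moderator composites, and both structural equations are fitted
# by least squares.

#' Build composite scores from an indicator dataset
#'
#' Computes the unweighted mean of each block's indicators
#' (`Xc = (x1 + x2 + x3)/3`, ...) and the product term `MZc`. By default the
#' mediator and moderator composites are mean-centred before multiplying,
#' which leaves the interaction coefficient unchanged and makes the
#' lower-order coefficients interpretable; set `center_before_product = FALSE`
#' for the raw product of composite means.
#'
#' @param data Indicator dataset.
#' @param center_before_product Mean-centre `Mc` and `Zc` before forming
#'   `MZc`? (Default `TRUE`; only `MZc` is affected, the returned composites
#'   themselves are never centred.)
#' @return A tibble with columns `Xc, Mc, Zc, Yc, MZc`.
#' @export
#' @examples
#' spec <- make_population_spec(design_cell(n = 100))
#' make_composites(generate_dataset(spec, seed = 1))
make_composites <- function(data, center_before_product = TRUE) {
  comp <- function(block) rowMeans(as.matrix(data[, BLOCK_COLS[[block]]]))
  Mc <- comp("M"); Zc <- comp("Z")
  mz <- if (center_before_product) {
    (Mc - mean(Mc)) * (Zc - mean(Zc))
  } else {
    Mc * Zc
  }
  tibble::tibble(Xc = comp("X"), Mc = Mc, Zc = Zc, Yc = comp("Y"), MZc = mz)
}

#' Fit the moderated mediation model by composite-score path analysis
#'
#' Fits `Mc = a Xc + e` and `Yc = c Xc + b1 Mc + b2 Zc + b3 MZc + e` by least
#' squares (the ML solution under normal errors) and derives the moderated
#' mediation index `a * b3` and the conditional indirect effects
#' `a * (b1 + b3 z)` at z = -1, 0, +1 sample SD of the moderator composite.
#' The fit always converges (completion rate 1 by construction) unless the
#' design matrix is collinear.
#'
#' @inheritParams make_composites
#' @return An `mmm_fit` with path estimates, least-squares standard errors,
#'   the covariance of the outcome-equation coefficients, and an `effects`
#'   tibble (`index`, `ind_m1sd`, `ind_0`, `ind_p1sd`).
#' @export
#' @examples
#' spec <- make_population_spec(design_cell(n = 300, b3 = 0.4))
#' fit <- fit_pa(generate_dataset(spec, seed = 2))
#' tidy(fit)
fit_pa <- function(data, center_before_product = TRUE) {
  comp <- make_composites(data, center_before_product = center_before_product)
  n <- nrow(comp)
  if (n <= 6) stop("need more than 6 cases for path analysis")
  fit_m <- lm(Mc ~ Xc, data = comp)
  fit_y <- lm(Yc ~ Xc + Mc + Zc + MZc, data = comp)
  rank_ok <- fit_m$rank == 2L && fit_y$rank == 5L
  cm <- coef(fit_m); cy <- coef(fit_y)
  vm <- stats::vcov(fit_m); vy <- stats::vcov(fit_y)
  est <- c(a = unname(cm["Xc"]), b1 = unname(cy["Mc"]), b2 = unname(cy["Zc"]),
           b3 = unname(cy["MZc"]), c = unname(cy["Xc"]))
  se <- c(
    a = sqrt(vm["Xc", "Xc"]), b1 = sqrt(vy["Mc", "Mc"]),
    b2 = sqrt(vy["Zc", "Zc"]), b3 = sqrt(vy["MZc", "MZc"]),
    c = sqrt(vy["Xc", "Xc"])
  )
  # joint covariance of (a; outcome-equation slopes), block diagonal because
  # the two equations have independent least-squares errors
  vcov <- matrix(0, 5, 5, dimnames = list(names(est), names(est)))
  vcov["a", "a"] <- vm["Xc", "Xc"]
  vcov[c("c", "b1", "b2", "b3"), c("c", "b1", "b2", "b3")] <-
    vy[c("Xc", "Mc", "Zc", "MZc"), c("Xc", "Mc", "Zc", "MZc")]

  sd_z <- sd(comp$Zc)
  effects <- conditional_effects_tbl(est["a"], est["b1"], est["b3"], sd_z)
  new_mmm_fit(
    method = "pa", estimates = est, se = se, vcov = vcov,
    loglik = as.numeric(logLik(fit_m)) + as.numeric(logLik(fit_y)),
    converged = rank_ok, proper_solution = rank_ok, n_obs = n,
    effects = effects, moderator_sd = sd_z
  )
}

# index and conditional indirect effects from point estimates of a, b1, b3
# and a moderator SD.
conditional_effects_tbl <- function(a, b1, b3, sd_z) {
  tibble::tibble(
    term = c("index", "ind_m1sd", "ind_0", "ind_p1sd"),
    estimate = unname(c(a * b3, a * (b1 - b3 * sd_z), a * b1, a * (b1 + b3 * sd_z)))
  )
}
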