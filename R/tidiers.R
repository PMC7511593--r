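#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a moderated mediation fit
#'
#' One row per parameter (and, by default, per derived effect) with the
#' estimate and, when available, standard error and 95% interval.
#'
#' @param x An `mmm_fit`.
#' @param effects Include the derived-effect rows (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and (when available)
#'   `se`, `ci_lower`, `ci_upper`.
#' @export
tidy.mmm_fit <- function(x, effects = TRUE, ...) {
  out <- tibble::tibble(term = names(x$estimates),
                        estimate = unname(x$estimates))
  if (!is.null(x$se)) {
    out$se <- unname(x$se[out$term])
    if (!is.null(x$ci_lower)) {
      out$ci_lower <- unname(x$ci_lower[out$term])
      out$ci_upper <- unname(x$ci_upper[out$term])
    }
  }
  if (effects && !is.null(x$effects)) {
    eff <- x$effects
    if ("se" %in% names(out) && !("se" %in% names(eff))) eff$se <- NA_real_
    out <- dplyr::bind_rows(out, eff)
  }
  out
}

#' Fit-level summary of a moderated mediation fit
#'
#' @param x An `mmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `loglik`, `converged`,
#'   `proper_solution` and `n_obs`.
#' @export
glance.mmm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, loglik = x$loglik, converged = x$converged,
    proper_solution = x$proper_solution, n_obs = x$n_obs
  )
}

#' Tidy a bootstrap result
#'
#' @param x A [bootstrap_fit()] result.
#' @param ... Unused.
#' @return A tibble with one row per tracked quantity: full-sample `estimate`,
#'   bootstrap `se` and percentile interval.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate), estimate = unname(x$estimate),
    se = unname(x$se[names(x$estimate)]),
    ci_lower = unname(x$ci_lower[names(x$estimate)]),
    ci_upper = unname(x$ci_upper[names(x$estimate)])
  )
}
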