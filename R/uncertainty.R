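# Case-resampling bootstrap and Wald tests, usable with any estimator that
# returns an `mmm_fit`.

# Values tracked across estimators: structural paths plus derived effects.
fit_values <- function(fit) {
  paths <- intersect(c("a", "b1", "b2", "b3", "c"), names(fit$estimates))
  vals <- if (length(paths)) fit$estimates[paths] else fit$estimates
  if (!is.null(fit$effects)) {
    vals <- c(vals, setNames(fit$effects$estimate, fit$effects$term))
  }
  vals
}

#' Case-resampling bootstrap for a moderated mediation estimator
#'
#' Resamples cases with replacement, re-runs the estimator on each resample,
#' and summarizes the tracked quantities (structural paths and derived
#' effects) by their bootstrap standard deviation and percentile confidence
#' interval. Draws in which the estimator errors or fails to produce a proper
#' solution are counted in `n_failed` and excluded from the summaries, so the
#' nominal number of draws stays interpretable.
#'
#' @param data Indicator dataset.
#' @param estimator Function `data -> mmm_fit`, e.g. [fit_pa()].
#' @param B Number of bootstrap draws (default 100).
#' @param seed Optional seed making the resampling reproducible.
#' @param level Confidence level of the percentile interval (default 0.95).
#' @return An object of class `bootstrap_result`: list with `B`, `draws`
#'   (B x quantities matrix, failed draws as NA rows), `estimate` (original
#'   full-sample values), `se`, `ci_lower`, `ci_upper` (percentile order
#'   statistics), `n_failed` and `usable`.
#' @export
#' @examples
#' spec <- make_population_spec(design_cell(n = 150, b3 = 0.2))
#' dat <- generate_dataset(spec, seed = 4)
#' bootstrap_fit(dat, fit_pa, B = 50, seed = 5)
bootstrap_fit <- function(data, estimator, B = 100, seed = NULL, level = 0.95) {
  stopifnot(B >= 2)
  n <- nrow(data)
  fit_full <- estimator(data)
  est <- fit_values(fit_full)
  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
  draws <- matrix(NA_real_, B, length(est),
                  dimnames = list(NULL, names(est)))
  for (b in seq_len(B)) {
    fit_b <- tryCatch(estimator(data[idx[b, ], , drop = FALSE]),
                      error = function(e) NULL)
    if (!is.null(fit_b) && isTRUE(fit_b$proper_solution)) {
      draws[b, ] <- fit_values(fit_b)[names(est)]
    }
  }
  ok <- stats::complete.cases(draws)
  usable <- sum(ok)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (usable >= 2) {
    se <- apply(draws[ok, , drop = FALSE], 2, sd)
    # percentile endpoints as order statistics of the draw vector
    ci <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = probs, type = 1)
    ci_lower <- setNames(ci[1, ], colnames(draws))
    ci_upper <- setNames(ci[2, ], colnames(draws))
  } else {
    se <- ci_lower <- ci_upper <- setNames(rep(NA_real_, length(est)), names(est))
  }
  structure(
    list(
      B = B, draws = draws, estimate = est, se = se,
      ci_lower = ci_lower, ci_upper = ci_upper,
      n_failed = B - usable, usable = usable, level = level
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d (%d failed)\n", x$B, x$n_failed))
  print(tidy(x))
  invisible(x)
}

#' Two-sided normal-theory Wald test
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `z`, `p_value` and logical `reject`.
#' @export
#' @examples
#' wald_test(0.2, 0.05)
wald_test <- function(estimate, se, alpha = 0.05) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  z <- estimate / se
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(z = z, p_value = p, reject = p < alpha)
}
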