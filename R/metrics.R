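# Evaluation measures of the Monte-Carlo study: relative bias, standard-error
# ratio, coverage, power/type-I error, plus the conventional acceptability
# windows.

#' Relative bias of a set of estimates
#'
#' `RB = (mean(estimates) - truth) / truth`. The conventional acceptability
#' threshold is `|RB| <= 0.10`. For zero-truth parameters relative bias is
#' undefined; report the raw mean bias instead (see [summarize_cell()]).
#'
#' @param estimates Numeric vector of replication estimates.
#' @param truth True parameter value (non-zero).
#' @return Scalar relative bias.
#' @export
#' @examples
#' relative_bias(rep(0.22, 10), 0.2)
relative_bias <- function(estimates, truth) {
  if (truth == 0) {
    stop("relative bias is undefined for a zero truth; report raw bias instead")
  }
  (mean(estimates) - truth) / truth
}

#' Standard-error ratio
#'
#' Mean estimated standard error divided by the empirical standard deviation
#' (denominator n-1) of the estimates across replications. Values in
#' \[0.9, 1.1\] are conventionally taken to indicate well-calibrated standard
#' errors.
#'
#' @param se_values Standard errors per replication.
#' @param estimates Estimates per replication (>= 2).
#' @return Scalar ratio.
#' @export
se_ratio <- function(se_values, estimates) {
  if (length(estimates) < 2) stop("need at least 2 estimates")
  s <- sd(estimates)
  if (s == 0) stop("zero empirical standard deviation")
  mean(se_values) / s
}

#' Coverage rate of interval estimates
#'
#' Fraction of replications whose closed interval contains the truth.
#'
#' @param ci_lowers,ci_uppers Interval endpoints per replication.
#' @param truth True parameter value.
#' @return Proportion in \[0, 1\].
#' @export
coverage_rate <- function(ci_lowers, ci_uppers, truth) {
  stopifnot(length(ci_lowers) == length(ci_uppers))
  mean(ci_lowers <= truth & truth <= ci_uppers)
}

#' Rejection rate of a significance test
#'
#' Fraction of replications with `p < alpha`; interpreted as power when the
#' true parameter is non-zero and as the type-I error rate when it is zero.
#'
#' @param p_values P-values per replication.
#' @param alpha Significance level (default 0.05).
#' @return Proportion in \[0, 1\].
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(NA_real_)
  mean(p_values < alpha)
}

#' Acceptability window of the empirical type-I error rate
#'
#' The 95% binomial interval around the nominal level:
#' `alpha +/- 1.96 sqrt(alpha (1 - alpha) / reps)` (\[0.0365, 0.0635\] at
#' alpha = 0.05 and 1000 replications).
#'
#' @param alpha Nominal level.
#' @param reps Number of replications.
#' @return Length-2 numeric vector (lower, upper).
#' @export
type1_window <- function(alpha = 0.05, reps = 1000) {
  half <- 1.96 * sqrt(alpha * (1 - alpha) / reps)
  c(alpha - half, alpha + half)
}
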