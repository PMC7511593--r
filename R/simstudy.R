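# Orchestration of the factorial Monte-Carlo study: per-replication records,
# per-cell metric summaries, and report output.

SIM_TERMS <- c("b3", "index", "ind_m1sd", "ind_0", "ind_p1sd")

empty_records <- function(rep_i, method) {
  tibble::tibble(
    rep = rep_i, estimator = method, term = SIM_TERMS,
    estimate = NA_real_, se = NA_real_,
    ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
    converged = FALSE, proper = FALSE
  )
}

records_from_fit <- function(fit, rep_i, method, boot = NULL) {
  est <- se <- lo <- hi <- setNames(rep(NA_real_, length(SIM_TERMS)), SIM_TERMS)
  est["b3"] <- fit$estimates[["b3"]]
  if (!is.null(fit$effects)) {
    est[fit$effects$term] <- fit$effects$estimate
  }
  if (!is.null(boot)) {
    keep <- intersect(SIM_TERMS, names(boot$se))
    se[keep] <- boot$se[keep]
    lo[keep] <- boot$ci_lower[keep]
    hi[keep] <- boot$ci_upper[keep]
  } else if (!is.null(fit$se) && isTRUE(fit$extra$se_ok)) {
    se["b3"] <- fit$se[["b3"]]
    lo["b3"] <- fit$ci_lower[["b3"]]
    hi["b3"] <- fit$ci_upper[["b3"]]
    if (!is.null(fit$effects$se)) {
      se[fit$effects$term] <- fit$effects$se
      lo[fit$effects$term] <- fit$effects$ci_lower
      hi[fit$effects$term] <- fit$effects$ci_upper
    }
  }
  p <- ifelse(is.finite(se) & se > 0, 2 * pnorm(-abs(est / se)), NA_real_)
  tibble::tibble(
    rep = rep_i, estimator = method, term = SIM_TERMS,
    estimate = unname(est), se = unname(se),
    ci_lower = unname(lo), ci_upper = unname(hi), p_value = unname(p),
    converged = isTRUE(fit$converged), proper = isTRUE(fit$proper_solution)
  )
}

#' Run all replications of one design cell
#'
#' For each replication: generates a dataset from the cell's population model
#' (on its own reproducible substream of the master seed), runs each requested
#' estimator, and records estimates, standard errors, confidence intervals,
#' p-values and proper-solution flags for the interaction coefficient, the
#' moderated mediation index and the three conditional indirect effects.
#' Estimator exceptions are caught and logged as non-complete replications.
#' Inference flavors follow the study design: case-resampling bootstrap
#' (percentile intervals, `boot_B` draws) for the path-analysis and
#' product-indicator estimators, robust sandwich standard errors for LMS.
#' `se = "none"` skips inference entirely (point estimates only), which is the
#' fast profile for bias-only summaries.
#'
#' @param cell A [design_cell()].
#' @param methods Subset of `c("pa", "cpi", "upi", "lms")`.
#' @param reps Number of replications.
#' @param master_seed Master seed; per-replication seeds are derived with
#'   [substream_seed()].
#' @param cell_id Integer id of the cell inside a larger design (seeds the
#'   substreams).
#' @param se `"default"` (bootstrap/robust as above) or `"none"`.
#' @param boot_B Bootstrap draws for PA/CPI/UPI (default 100).
#' @param lms_K LMS quadrature order (default 16).
#' @param pairing Product-indicator pairing; defaults to matching by the
#'   population loadings of the cell's model.
#' @return A tibble of per-replication records with attributes `cell` and
#'   `spec`.
#' @export
#' @examples
#' rec <- run_cell(design_cell(n = 100, b3 = 0.2), methods = "pa",
#'                 reps = 5, master_seed = 1, se = "none")
#' summarize_cell(rec)
run_cell <- function(cell, methods = c("pa", "lms"), reps = 100,
                     master_seed = 1, cell_id = 1L,
                     se = c("default", "none"), boot_B = 100, lms_K = 16,
                     pairing = NULL) {
  se <- match.arg(se)
  methods <- match.arg(methods, c("pa", "cpi", "upi", "lms"), several.ok = TRUE)
  spec <- make_population_spec(cell)
  if (is.null(pairing)) {
    pairing <- match_indicators(spec$measurement$M$loadings,
                                spec$measurement$Z$loadings)
  }
  one_rep <- function(rep_i) {
    dat <- generate_dataset(spec, n = cell$n,
                            seed = substream_seed(master_seed, cell_id, rep_i))
    purrr::map_dfr(methods, function(method) {
      boot_seed <- substream_seed(
        master_seed, cell_id * 101L + match(method, c("pa", "cpi", "upi", "lms")),
        rep_i
      )
      res <- tryCatch({
        if (method == "lms") {
          fit <- fit_lms(dat, K = lms_K,
                         se = if (se == "default") "robust" else "none")
          records_from_fit(fit, rep_i, method)
        } else {
          estimator <- switch(method,
            pa = fit_pa,
            cpi = function(d) fit_cpi(d, pairing = pairing),
            upi = function(d) fit_upi(d, pairing = pairing)
          )
          fit <- estimator(dat)
          boot <- NULL
          if (se == "default" && isTRUE(fit$proper_solution)) {
            boot <- bootstrap_fit(dat, estimator, B = boot_B, seed = boot_seed)
          }
          records_from_fit(fit, rep_i, method, boot = boot)
        }
      }, error = function(e) empty_records(rep_i, method))
      res
    })
  }
  records <- purrr::map_dfr(seq_len(reps), one_rep)
  attr(records, "cell") <- cell
  attr(records, "spec") <- spec
  records
}

summarize_one <- function(sub, truth_t, alpha) {
  est <- sub$estimate[is.finite(sub$estimate)]
  n_used <- length(est)
  if (truth_t == 0) {
    bias <- if (n_used) mean(est) else NA_real_
    bias_type <- "raw"
    bias_ok <- NA
  } else {
    bias <- if (n_used) relative_bias(est, truth_t) else NA_real_
    bias_type <- "relative"
    bias_ok <- if (n_used) abs(bias) <= 0.10 else NA
  }
  ok_se <- is.finite(sub$estimate) & is.finite(sub$se)
  sr <- if (sum(ok_se) >= 2 && sd(sub$estimate[ok_se]) > 0) {
    se_ratio(sub$se[ok_se], sub$estimate[ok_se])
  } else NA_real_
  ok_ci <- is.finite(sub$ci_lower) & is.finite(sub$ci_upper)
  cov <- if (any(ok_ci)) {
    coverage_rate(sub$ci_lower[ok_ci], sub$ci_upper[ok_ci], truth_t)
  } else NA_real_
  pv <- sub$p_value[is.finite(sub$p_value)]
  rate <- rejection_rate(pv)
  rate_type <- if (truth_t == 0) "type1" else "power"
  rate_ok <- if (!is.na(rate)) {
    if (rate_type == "power") {
      rate >= 0.8
    } else {
      w <- type1_window(alpha, length(pv))
      rate >= w[1] && rate <= w[2]
    }
  } else NA
  tibble::tibble(
    truth = truth_t, bias = bias, bias_type = bias_type, bias_ok = bias_ok,
    se_ratio = sr, se_ratio_ok = ifelse(is.na(sr), NA, sr >= 0.9 & sr <= 1.1),
    coverage = cov, coverage_ok = ifelse(is.na(cov), NA, cov >= 0.9),
    rate = rate, rate_type = rate_type, rate_ok = rate_ok,
    n_reps_used = n_used
  )
}

#' Summarize per-replication records into evaluation metrics
#'
#' One row per estimator and target parameter with relative bias (raw mean
#' bias, flagged, when the truth is zero), standard-error ratio, coverage of
#' the 95% intervals, power or type-I rate of the two-sided Wald test at
#' `alpha`, the completion rate, and the conventional acceptability flags.
#' Metrics are computed over proper-solution replications only; the
#' completion rate is reported against all replications. An extra `ind` row
#' per estimator averages the metrics of the three conditional indirect
#' effects.
#'
#' @param records Output of [run_cell()].
#' @param spec The population model (defaults to the records' attribute).
#' @param alpha Test level (default 0.05).
#' @return A tibble of class `mm_metrics`.
#' @export
summarize_cell <- function(records, spec = attr(records, "spec"), alpha = 0.05) {
  stopifnot(nrow(records) > 0, !is.null(spec))
  truth <- population_effects(spec)
  truth_of <- setNames(truth$truth, truth$term)
  out <- records |>
    dplyr::group_by(.data$estimator) |>
    dplyr::group_modify(function(g, key) {
      completion <- g |>
        dplyr::distinct(.data$rep, .data$proper) |>
        dplyr::summarise(completion = mean(.data$proper)) |>
        dplyr::pull(completion)
      per_term <- purrr::map_dfr(SIM_TERMS, function(tm) {
        sub <- dplyr::filter(g, .data$term == tm, .data$proper)
        dplyr::bind_cols(tibble::tibble(term = tm),
                         summarize_one(sub, truth_of[[tm]], alpha))
      })
      ind <- per_term |>
        dplyr::filter(.data$term %in% c("ind_m1sd", "ind_0", "ind_p1sd")) |>
        dplyr::summarise(
          term = "ind",
          truth = mean(.data$truth),
          bias = mean(.data$bias), bias_type = .data$bias_type[1],
          bias_ok = if (all(is.na(.data$bias_ok))) NA else
            abs(mean(.data$bias)) <= 0.10,
          se_ratio = mean(.data$se_ratio),
          se_ratio_ok = ifelse(is.na(mean(.data$se_ratio)), NA,
                               mean(.data$se_ratio) >= 0.9 &
                                 mean(.data$se_ratio) <= 1.1),
          coverage = mean(.data$coverage),
          coverage_ok = ifelse(is.na(mean(.data$coverage)), NA,
                               mean(.data$coverage) >= 0.9),
          rate = mean(.data$rate), rate_type = .data$rate_type[1],
          rate_ok = NA, n_reps_used = min(.data$n_reps_used)
        )
      dplyr::bind_rows(per_term, ind) |>
        dplyr::mutate(completion_rate = completion)
    }) |>
    dplyr::ungroup()
  attr(out, "cell") <- attr(records, "cell")
  class(out) <- c("mm_metrics", class(out))
  out
}

#' Run several design cells and stack their metrics
#'
#' @param cells List of [design_cell()]s.
#' @param ... Passed to [run_cell()].
#' @return A list with `records` (list of per-cell record tibbles) and
#'   `metrics` (one tibble with the cell factors as leading columns).
#' @export
run_design <- function(cells, ...) {
  records <- purrr::imap(cells, function(cell, i) {
    run_cell(cell, cell_id = as.integer(i), ...)
  })
  metrics <- purrr::imap_dfr(records, function(rec, i) {
    cell <- attr(rec, "cell")
    dplyr::bind_cols(
      tibble::tibble(
        cell_id = as.integer(i), n = cell$n, b3 = cell$b3,
        reliability = cell$reliability,
        distribution_type = cell$distribution_type, cor_xz = cell$cor_xz
      ),
      summarize_cell(rec)
    )
  })
  list(records = records, metrics = metrics)
}

#' Write a metrics table to disk
#'
#' Writes the tidy metrics as CSV and, alongside it, a formatted plain-text
#' report (one block per evaluation measure, estimators as rows and target
#' parameters as columns).
#'
#' @param metrics A [summarize_cell()] or [run_design()] metrics tibble.
#' @param path Output CSV path; the text report replaces the extension with
#'   `.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(metrics, path) {
  readr::write_csv(tibble::as_tibble(metrics), path)
  txt_path <- sub("\\.[^.]*$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  measures <- c(bias = "bias", `SE ratio` = "se_ratio",
                coverage = "coverage", `power / type-I` = "rate",
                completion = "completion_rate")
  lines <- character(0)
  for (i in seq_along(measures)) {
    lines <- c(lines, names(measures)[i])
    wide <- metrics |>
      dplyr::select(dplyr::any_of(c("cell_id", "n", "b3", "reliability",
                                    "distribution_type", "cor_xz")),
                    "estimator", "term", value = dplyr::all_of(measures[[i]])) |>
      dplyr::mutate(value = round(.data$value, 3)) |>
      tidyr::pivot_wider(names_from = "term", values_from = "value")
    lines <- c(lines, utils::capture.output(print(as.data.frame(wide),
                                                  row.names = FALSE)), "")
  }
  writeLines(lines, txt_path)
  invisible(path)
}
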