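#' @importFrom rlang .data
#' @importFrom stats rnorm runif rchisq rbinom var sd cov quantile pnorm qnorm pchisq qchisq dnorm setNames coef lm optimHess nlminb logLik
NULL

# Fixed indicator layout: 3 indicators for X and Z, 4 for M and Y.
IND_COLS <- c(
  "x1", "x2", "x3",
  "m1", "m2", "m3", "m4",
  "z1", "z2", "z3",
  "y1", "y2", "y3", "y4"
)

BLOCK_COLS <- list(
  X = c("x1", "x2", "x3"),
  M = c("m1", "m2", "m3", "m4"),
  Z = c("z1", "z2", "z3"),
  Y = c("y1", "y2", "y3", "y4")
)

ERROR_DISTRIBUTIONS <- c(
  "normal",                  # type 1
  "uniform01",               # type 2
  "symm_moderate_kurtosis",  # type 3
  "symm_high_kurtosis",      # type 4
  "skewed_chisq1"            # type 5
)

#' Define a simulation design cell
#'
#' A design cell is one condition of the factorial simulation design: sample
#' size, interaction effect size, indicator reliability, indicator error
#' distribution and the correlation between the independent variable and the
#' moderator.
#'
#' @param n Sample size per replication (positive integer).
#' @param b3 Path coefficient of the latent interaction on the outcome.
#'   The canonical design uses 0 (type-I error conditions), 0.2 and 0.4.
#' @param reliability `"high"` (indicator error variances 0.36) or `"low"`
#'   (indicator error variances 1.5).
#' @param distribution_type Integer 1-5 selecting the measurement-error
#'   distribution for the mediator- and moderator-block indicators:
#'   1 normal, 2 uniform on \[0, 1\], 3 symmetric moderate kurtosis,
#'   4 symmetric high kurtosis, 5 slightly skewed (chi-square, 1 df).
#'   The X- and Y-block errors are always normal.
#' @param cor_xz Latent correlation between X and Z (0 or 0.3 in the canonical
#'   design; any value giving a positive-definite latent covariance works).
#'
#' @return An object of class `design_cell` (a named list).
#' @export
#' @examples
#' design_cell(n = 500, b3 = 0.2, reliability = "high")
design_cell <- function(n = 200, b3 = 0.2, reliability = c("high", "low"),
                        distribution_type = 1L, cor_xz = 0) {
  reliability <- match.arg(reliability)
  stopifnot(
    length(n) == 1L, is.finite(n), n >= 1,
    length(b3) == 1L, is.finite(b3),
    length(distribution_type) == 1L, distribution_type %in% 1:5,
    length(cor_xz) == 1L, is.finite(cor_xz), abs(cor_xz) < 1
  )
  structure(
    list(
      n = as.integer(n), b3 = b3, reliability = reliability,
      distribution_type = as.integer(distribution_type), cor_xz = cor_xz
    ),
    class = "design_cell"
  )
}

#' @export
print.design_cell <- function(x, ...) {
  cat(sprintf(
    "<design_cell> n = %d, b3 = %g, reliability = %s, error type = %d, cor(X,Z) = %g\n",
    x$n, x$b3, x$reliability, x$distribution_type, x$cor_xz
  ))
  invisible(x)
}

measurement_spec <- function(block, loadings, intercepts, error_variances,
                             error_distribution = "normal") {
  stopifnot(
    block %in% names(BLOCK_COLS),
    loadings[1] == 1,
    length(loadings) == length(intercepts),
    length(loadings) == length(error_variances),
    all(error_variances > 0),
    error_distribution %in% ERROR_DISTRIBUTIONS
  )
  list(
    block = block, loadings = loadings, intercepts = intercepts,
    error_variances = error_variances, error_distribution = error_distribution
  )
}

#' Build the population model for a design cell
#'
#' Returns the full parameterization of the data-generating model: a
#' measurement model for each latent variable (X, M, Z, Y) and the structural
#' model `M = a X + e_M`, `Y = c X + b1 M + b2 Z + b3 MZ + e_Y`. Factor
#' loadings are (1, 0.65, 0.72) for X, (1, 0.81, 0.53, 0.66) for M,
#' (1, 0.83, 0.79) for Z and (1, 0.68, 0.75, 0.83) for Y; all intercepts are
#' 0.5; a = 0.75, b1 = 0.56, b2 = 0.48, c = 0.3; Var(X) = Var(Z) = 1 and both
#' structural residual variances are 0.36. Indicator error variances are 0.36
#' under high reliability and 1.5 under low reliability. The error
#' distribution of the M- and Z-block indicators follows the cell's
#' `distribution_type`; X- and Y-block errors are always normal.
#'
#' @param cell A [design_cell()].
#' @return An object of class `population_spec`.
#' @export
#' @examples
#' spec <- make_population_spec(design_cell(n = 500, b3 = 0.2))
#' spec$measurement$M$loadings
make_population_spec <- function(cell) {
  stopifnot(inherits(cell, "design_cell"))
  ev <- switch(cell$reliability, high = 0.36, low = 1.5)
  mz_dist <- ERROR_DISTRIBUTIONS[cell$distribution_type]
  structure(
    list(
      measurement = list(
        X = measurement_spec("X", c(1, 0.65, 0.72), rep(0.5, 3), rep(ev, 3), "normal"),
        M = measurement_spec("M", c(1, 0.81, 0.53, 0.66), rep(0.5, 4), rep(ev, 4), mz_dist),
        Z = measurement_spec("Z", c(1, 0.83, 0.79), rep(0.5, 3), rep(ev, 3), mz_dist),
        Y = measurement_spec("Y", c(1, 0.68, 0.75, 0.83), rep(0.5, 4), rep(ev, 4), "normal")
      ),
      structural = list(
        a = 0.75, b1 = 0.56, b2 = 0.48, b3 = cell$b3, c = 0.3,
        var_x = 1, var_z = 1, cov_xz = cell$cor_xz,
        resid_var_m = 0.36, resid_var_y = 0.36
      ),
      cell = cell
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  s <- x$structural
  cat("<population_spec>\n")
  cat(sprintf("  structural: a = %g, b1 = %g, b2 = %g, b3 = %g, c = %g\n",
              s$a, s$b1, s$b2, s$b3, s$c))
  cat(sprintf("  latent: Var(X) = %g, Var(Z) = %g, Cov(X,Z) = %g; resid M/Y = %g/%g\n",
              s$var_x, s$var_z, s$cov_xz, s$resid_var_m, s$resid_var_y))
  for (b in names(x$measurement)) {
    m <- x$measurement[[b]]
    cat(sprintf("  %s: loadings (%s), error var %g, errors %s\n",
                b, paste(m$loadings, collapse = ", "),
                m$error_variances[1], m$error_distribution))
  }
  invisible(x)
}

#' Draw measurement errors from one of the five error distributions
#'
#' All draws have mean zero. Type 1 is normal with variance `variance_scale`.
#' Type 2 is uniform on \[0, 1\] centred at zero (natural variance 1/12).
#' Types 3 and 4 are symmetric heavy-tailed variates built as a standard
#' normal divided by `sqrt(chisq(df)/3)` (df = `df_moderate` resp. `df_high`),
#' rescaled to variance `variance_scale`. Type 5 is chi-square with 1 df
#' centred at zero (natural variance 2, skewness `sqrt(8)`). For types 2 and 5
#' the natural variance is kept unless `rescale_nonnormal = TRUE`, in which
#' case draws are rescaled to `variance_scale`.
#'
#' @param dist_type Integer 1-5 or one of
#'   `r paste0('"', ERROR_DISTRIBUTIONS, '"', collapse = ", ")`.
#' @param variance_scale Target error variance for types 1, 3, 4 (and for
#'   2 and 5 when `rescale_nonnormal` is set).
#' @param n Number of draws.
#' @param df_moderate,df_high Chi-square degrees of freedom of the divisor in
#'   the type-3 and type-4 constructions. The type-4 default (4) yields much
#'   heavier tails than the type-3 default (5).
#' @param rescale_nonnormal Rescale types 2 and 5 to `variance_scale`?
#' @return Numeric vector of length `n`.
#' @export
sample_error <- function(dist_type, variance_scale, n,
                         df_moderate = 5, df_high = 4,
                         rescale_nonnormal = FALSE) {
  stopifnot(n >= 1)
  if (is.numeric(dist_type)) {
    stopifnot(dist_type %in% 1:5)
    dist_type <- ERROR_DISTRIBUTIONS[dist_type]
  }
  dist_type <- match.arg(dist_type, ERROR_DISTRIBUTIONS)
  scaled_t_construction <- function(df) {
    # normal / sqrt(chisq(df)/3): variance 3/(df-2) for df > 2
    x <- rnorm(n) / sqrt(rchisq(n, df = df) / 3)
    x * sqrt(variance_scale / (3 / (df - 2)))
  }
  switch(dist_type,
    normal = rnorm(n, 0, sqrt(variance_scale)),
    uniform01 = {
      x <- runif(n) - 0.5
      if (rescale_nonnormal) x * sqrt(variance_scale / (1 / 12)) else x
    },
    symm_moderate_kurtosis = scaled_t_construction(df_moderate),
    symm_high_kurtosis = scaled_t_construction(df_high),
    skewed_chisq1 = {
      x <- rchisq(n, df = 1) - 1
      if (rescale_nonnormal) x * sqrt(variance_scale / 2) else x
    }
  )
}

# Run code with a caller-supplied seed without disturbing the global RNG
# stream when no seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with a cell index and replication index into
#' a seed below 2^31, so each replication of each design cell has its own
#' reproducible random-number stream regardless of execution order.
#'
#' @param master Master seed (integer).
#' @param cell_id Integer identifying the design cell.
#' @param rep Replication index.
#' @return A single integer seed.
#' @export
substream_seed <- function(master, cell_id = 1L, rep = 1L) {
  m <- 2147483647 # 2^31 - 1; all arithmetic stays exact in doubles
  h <- as.numeric(master) %% m
  for (v in c(cell_id, rep, 0x9e37)) {
    h <- (h * 48271 + as.numeric(v) * 16807 + 12345) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

#' Generate an indicator dataset from the population model
#'
#' Draws the latent variables (X, Z jointly Gaussian, structural residuals
#' Gaussian), computes M and Y from the structural equations, and produces the
#' 14 indicators from the measurement models with block-specific error draws.
#'
#' @param spec A [make_population_spec()] result.
#' @param n Number of cases; defaults to the cell's sample size.
#' @param seed Optional integer seed; when supplied the result is a
#'   deterministic function of `(spec, n, seed)` and the caller's RNG state is
#'   left untouched.
#' @param ... Passed to [sample_error()] (`df_moderate`, `df_high`,
#'   `rescale_nonnormal`).
#' @return A tibble with `n` rows and the 14 indicator columns
#'   `x1..x3, m1..m4, z1..z3, y1..y4`.
#' @export
#' @examples
#' spec <- make_population_spec(design_cell(n = 200, b3 = 0.2))
#' dat <- generate_dataset(spec, seed = 1)
#' dplyr::glimpse(dat)
generate_dataset <- function(spec, n = spec$cell$n, seed = NULL, ...) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  s <- spec$structural
  det2 <- s$var_x * s$var_z - s$cov_xz^2
  if (det2 <= 0) stop("latent (X, Z) covariance matrix is not positive definite")
  with_seed(seed, {
    # (X, Z) via Cholesky of the 2x2 latent covariance
    e1 <- rnorm(n); e2 <- rnorm(n)
    X <- sqrt(s$var_x) * e1
    Z <- (s$cov_xz / sqrt(s$var_x)) * e1 + sqrt(det2 / s$var_x) * e2
    M <- s$a * X + rnorm(n, 0, sqrt(s$resid_var_m))
    Y <- s$c * X + s$b1 * M + s$b2 * Z + s$b3 * M * Z +
      rnorm(n, 0, sqrt(s$resid_var_y))
    latents <- list(X = X, M = M, Z = Z, Y = Y)
    cols <- lapply(names(spec$measurement), function(b) {
      ms <- spec$measurement[[b]]
      eta <- latents[[b]]
      vapply(seq_along(ms$loadings), function(j) {
        ms$intercepts[j] + ms$loadings[j] * eta +
          sample_error(ms$error_distribution, ms$error_variances[j], n, ...)
      }, numeric(n))
    })
    out <- do.call(cbind, cols)
    colnames(out) <- IND_COLS
    tibble::as_tibble(out)
  })
}

# Latent first/second moments of (X, M, Z, MZ, Y) under the population model.
# Uses the Gaussian moment identities: with zero-mean jointly Gaussian (M, Z),
# E(MZ) = Cov(M, Z), Var(MZ) = Var(M)Var(Z) + Cov(M, Z)^2, and MZ is
# uncorrelated with X, M and Z (odd Gaussian moments vanish).
latent_population_moments <- function(s) {
  var_m <- s$a^2 * s$var_x + s$resid_var_m
  cov_mz <- s$a * s$cov_xz
  var_mz <- var_m * s$var_z + cov_mz^2
  e_mz <- cov_mz
  # order: X, M, Z, MZ, Y
  nu <- c(X = 0, M = 0, Z = 0, MZ = e_mz, Y = s$b3 * e_mz)
  P <- matrix(0, 5, 5, dimnames = list(names(nu), names(nu)))
  P["X", "X"] <- s$var_x
  P["X", "M"] <- P["M", "X"] <- s$a * s$var_x
  P["X", "Z"] <- P["Z", "X"] <- s$cov_xz
  P["M", "M"] <- var_m
  P["M", "Z"] <- P["Z", "M"] <- cov_mz
  P["Z", "Z"] <- s$var_z
  P["MZ", "MZ"] <- var_mz
  bvec <- c(X = s$c, M = s$b1, Z = s$b2, MZ = s$b3)
  for (v in c("X", "M", "Z", "MZ")) {
    P["Y", v] <- P[v, "Y"] <- sum(bvec * P[c("X", "M", "Z", "MZ"), v])
  }
  P["Y", "Y"] <- drop(bvec %*% P[c("X", "M", "Z", "MZ"), c("X", "M", "Z", "MZ")] %*% bvec) +
    s$resid_var_y
  list(nu = nu, P = P)
}

# 14 x 5 loading matrix of the indicators on (X, M, Z, MZ, Y); MZ has no
# indicators.
population_loading_matrix <- function(spec) {
  L <- matrix(0, 14, 5, dimnames = list(IND_COLS, c("X", "M", "Z", "MZ", "Y")))
  for (b in names(spec$measurement)) {
    L[BLOCK_COLS[[b]], b] <- spec$measurement[[b]]$loadings
  }
  L
}

#' Closed-form population moments of the 14 indicators
#'
#' Exact implied mean vector and covariance matrix of the indicators under the
#' population model, valid when all measurement errors are normal (type 1).
#' The latent interaction moments use the Gaussian identities
#' `E(MZ) = Cov(M, Z)` and `Var(MZ) = Var(M)Var(Z) + Cov(M, Z)^2`. Serves as
#' an analytic oracle for [generate_dataset()] and for the structural-equation
#' engine.
#'
#' @param spec A [make_population_spec()] result with normal errors in every
#'   block.
#' @return A list with `mean` (length-14 named vector) and `cov` (14 x 14
#'   named matrix).
#' @export
population_moments <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  dists <- vapply(spec$measurement, function(m) m$error_distribution, "")
  if (!all(dists == "normal")) {
    stop("population_moments() supports normal (type 1) measurement errors only")
  }
  lat <- latent_population_moments(spec$structural)
  L <- population_loading_matrix(spec)
  tau <- unlist(lapply(spec$measurement, function(m) m$intercepts), use.names = FALSE)
  theta <- unlist(lapply(spec$measurement, function(m) m$error_variances), use.names = FALSE)
  mu <- tau + drop(L %*% lat$nu)
  sigma <- L %*% lat$P %*% t(L) + diag(theta)
  names(mu) <- IND_COLS
  dimnames(sigma) <- list(IND_COLS, IND_COLS)
  list(mean = mu, cov = sigma)
}

#' Cronbach's alpha of one indicator block
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the item sum)`
#' computed on the block's columns.
#'
#' @param data Indicator dataset (data frame with the standard column names).
#' @param block One of `"X"`, `"M"`, `"Z"`, `"Y"`.
#' @return Alpha (numeric scalar).
#' @export
cronbach_alpha <- function(data, block = c("X", "M", "Z", "Y")) {
  block <- match.arg(block)
  cols <- BLOCK_COLS[[block]]
  k <- length(cols)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  x <- as.matrix(data[, cols])
  total_var <- var(rowSums(x))
  if (total_var == 0) return(1)
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Population (asymptotic) Cronbach's alpha of a block
#'
#' Evaluates the alpha formula on the exact population covariance matrix from
#' [population_moments()], i.e. the large-sample limit of [cronbach_alpha()].
#'
#' @inheritParams cronbach_alpha
#' @param spec A [make_population_spec()] result (normal errors).
#' @return Alpha (numeric scalar).
#' @export
population_alpha <- function(spec, block = c("X", "M", "Z", "Y")) {
  block <- match.arg(block)
  cols <- BLOCK_COLS[[block]]
  S <- population_moments(spec)$cov[cols, cols]
  k <- length(cols)
  (k / (k - 1)) * (1 - sum(diag(S)) / sum(S))
}

#' True values of the reported effects under a population model
#'
#' Returns the interaction coefficient `b3`, the moderated mediation index
#' `a * b3`, and the conditional indirect effects `a * (b1 + b3 * z)` at the
#' moderator values z = -1, 0, +1 population SD.
#'
#' @param spec A [make_population_spec()] result.
#' @return A tibble with columns `term` and `truth`.
#' @export
population_effects <- function(spec) {
  s <- spec$structural
  sdz <- sqrt(s$var_z)
  tibble::tibble(
    term = c("b3", "index", "ind_m1sd", "ind_0", "ind_p1sd"),
    truth = c(
      s$b3,
      s$a * s$b3,
      s$a * (s$b1 - s$b3 * sdz),
      s$a * s$b1,
      s$a * (s$b1 + s$b3 * sdz)
    )
  )
}

#' Read or write indicator datasets as CSV
#'
#' Plain CSV with a header of the 14 standard indicator column names.
#'
#' @param data Indicator dataset.
#' @param path File path.
#' @return `read_indicator_csv()` returns a tibble; `write_indicator_csv()`
#'   returns `path` invisibly.
#' @export
write_indicator_csv <- function(data, path) {
  stopifnot(all(IND_COLS %in% names(data)))
  readr::write_csv(data[, IND_COLS], path)
  invisible(path)
}

#' @rdname write_indicator_csv
#' @export
read_indicator_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(IND_COLS, names(out))
  if (length(missing)) {
    stop("missing indicator columns: ", paste(missing, collapse = ", "))
  }
  out[, IND_COLS]
}

#' Serialize a population spec to YAML
#'
#' @param spec A [make_population_spec()] result.
#' @param path File path.
#' @return `read_population_spec()` returns a `population_spec`;
#'   `write_population_spec()` returns `path` invisibly.
#' @export
write_population_spec <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  obj <- list(
    measurement = lapply(spec$measurement, function(m) {
      list(
        block = m$block, loadings = m$loadings, intercepts = m$intercepts,
        error_variances = m$error_variances,
        error_distribution = m$error_distribution
      )
    }),
    structural = spec$structural,
    cell = unclass(spec$cell)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  cell <- do.call(design_cell, obj$cell)
  spec <- make_population_spec(cell)
  spec$measurement <- lapply(obj$measurement, function(m) {
    measurement_spec(m$block, m$loadings, m$intercepts, m$error_variances,
                     m$error_distribution)
  })
  names(spec$measurement) <- vapply(spec$measurement, `[[`, "", "block")
  spec$structural <- obj$structural
  spec
}
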