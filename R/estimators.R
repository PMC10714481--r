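#' Single-variant ratio (Wald) estimate
#'
#' The building block of the summary-data estimators: the causal effect of
#' the exposure on the outcome implied by one variant is the ratio of its
#' outcome and exposure associations. The default standard error is the
#' first-order delta approximation `|se_outcome / beta_exposure|` (simple
#' weighting); `order = 2` adds the exposure-uncertainty term.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Scalar
#'   association statistics for one variant.
#' @param order 1 (default) or 2, the delta-method order for the SE.
#' @return A one-row [tibble][tibble::tibble] with `method`, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `p_value`, `n_snp`, `q_stat`.
#' @export
mr_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                     order = 1L) {
  if (beta_exposure == 0) {
    abort("Ratio estimate undefined for beta_exposure = 0")
  }
  theta <- beta_outcome / beta_exposure
  se <- if (order == 1L) {
    abs(se_outcome / beta_exposure)
  } else {
    sqrt(se_outcome^2 / beta_exposure^2 +
           beta_outcome^2 * se_exposure^2 / beta_exposure^4)
  }
  mr_result_row("ratio", theta, se, z_to_p(theta / se), 1L)
}

ratio_components <- function(data, order = 1L) {
  theta_j <- data$beta_outcome / data$beta_exposure
  var_j <- if (order == 1L) {
    data$se_outcome^2 / data$beta_exposure^2
  } else {
    data$se_outcome^2 / data$beta_exposure^2 +
      data$beta_outcome^2 * data$se_exposure^2 / data$beta_exposure^4
  }
  list(theta = theta_j, w = 1 / var_j)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' The main estimator: the weighted regression of outcome betas on exposure
#' betas through the origin with weights `1 / se_outcome^2`, equivalently
#' the inverse-variance weighted average of the per-variant ratio
#' estimates. Under multiplicative random effects (the default) the fixed
#' effect standard error is inflated by `max(1, sqrt(Q / (k - 1)))`, so
#' heterogeneity widens but never narrows the interval.
#'
#' @param data Harmonized tibble with `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` (see [harmonize()]).
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return A one-row result tibble (see [mr_ratio()]); `q_stat` carries the
#'   Cochran statistic. With a single variant the ratio estimate is
#'   returned with a warning.
#' @export
mr_ivw <- function(data, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  assert_harmonized(data, caller = "mr_ivw")
  k <- nrow(data)
  if (k < 2) {
    warn("mr_ivw needs at least 2 instruments; returning the ratio estimate")
    return(mr_ratio(data$beta_exposure, data$se_exposure,
                    data$beta_outcome, data$se_outcome))
  }
  w <- 1 / data$se_outcome^2
  sxx <- sum(data$beta_exposure^2 * w)
  theta <- sum(data$beta_exposure * data$beta_outcome * w) / sxx
  se_fixed <- sqrt(1 / sxx)
  theta_j <- data$beta_outcome / data$beta_exposure
  w_j <- data$beta_exposure^2 * w
  Q <- sum(w_j * (theta_j - theta)^2)
  se <- if (mode == "fixed") se_fixed else se_fixed * max(1, sqrt(Q / (k - 1)))
  method <- if (mode == "fixed") "ivw_fe" else "ivw_mre"
  mr_result_row(method, theta, se, z_to_p(theta / se), k, Q)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1 / se_outcome^2`, after orienting every variant so
#' its exposure beta is non-negative. The slope is the causal estimate and
#' the intercept estimates directional pleiotropy (its deviation from zero
#' is the Egger intercept test). Standard errors use a multiplicative
#' overdispersion factor `max(1, sqrt(RSS / (k - 2)))`; p-values use the t
#' reference with `k - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return A two-row result tibble: methods `egger` (slope) and
#'   `egger_intercept`; `q_stat` on the slope row is the Egger residual
#'   heterogeneity statistic (df `k - 2`).
#' @export
mr_egger <- function(data) {
  assert_harmonized(data, min_snps = 3L, caller = "mr_egger")
  k <- nrow(data)
  flip <- sign(data$beta_exposure)
  flip[flip == 0] <- 1
  bx <- data$beta_exposure * flip
  by <- data$beta_outcome * flip
  w <- 1 / data$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  est <- coef(fit)
  rss <- sum(w * fit$residuals^2)
  sigma <- sqrt(rss / (k - 2))
  # dispersion-free covariance, then the overdispersion floored at 1
  X <- cbind(1, bx)
  vc <- solve(crossprod(X * sqrt(w)))
  ses <- sqrt(diag(vc)) * max(1, sigma)
  p <- 2 * pt(-abs(est / ses), df = k - 2)
  dplyr::bind_rows(
    mr_result_row("egger", unname(est[2]), unname(ses[2]),
                  unname(p[2]), k, rss),
    mr_result_row("egger_intercept", unname(est[1]), unname(ses[1]),
                  unname(p[1]), k)
  )
}

weighted_median_point <- function(theta_j, w_j) {
  o <- order(theta_j)
  th <- theta_j[o]
  ww <- w_j[o] / sum(w_j)
  s <- cumsum(ww) - ww / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(s)])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

boot_resample <- function(data, n_boot, statistic) {
  k <- nrow(data)
  bx <- matrix(rnorm(k * n_boot, data$beta_exposure, data$se_exposure), k)
  by <- matrix(rnorm(k * n_boot, data$beta_outcome, data$se_outcome), k)
  vapply(seq_len(n_boot), function(b) statistic(bx[, b], by[, b]),
         numeric(1))
}

#' Weighted median estimator
#'
#' The weighted median of the per-variant ratio estimates, using inverse
#' first-order delta-method variances as weights: consistent when variants
#' carrying at least half the weight are valid instruments, so it tolerates
#' up to 50% invalid weight where IVW does not. The estimate interpolates
#' the sorted ratios against the centered cumulative weights at one half;
#' the standard error comes from a parametric bootstrap that redraws
#' exposure and outcome betas from normals with their reported standard
#' errors.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE; default 1000.
#' @param seed Optional integer seed making the bootstrap reproducible
#'   without touching the caller's RNG state.
#' @export
mr_weighted_median <- function(data, n_boot = 1000L, seed = NULL) {
  assert_harmonized(data, min_snps = 3L, caller = "mr_weighted_median")
  rc <- ratio_components(data)
  theta <- weighted_median_point(rc$theta, rc$w)
  boots <- with_seed_if(seed, boot_resample(data, n_boot, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / data$se_outcome^2)
  }))
  se <- sd(boots)
  mr_result_row("weighted_median", theta, se, z_to_p(theta / se), nrow(data))
}

silverman_bw <- function(theta_j, phi) {
  s <- 0.9 * min(sd(theta_j), mad(theta_j)) * length(theta_j)^(-1 / 5)
  phi * s
}

weighted_mode_point <- function(theta_j, w_j, phi) {
  if (max(theta_j) - min(theta_j) < .Machine$double.eps^0.5) {
    return(theta_j[1])
  }
  h <- silverman_bw(theta_j, phi)
  if (!is.finite(h) || h <= 0) {
    h <- phi * 0.9 * sd(theta_j) * length(theta_j)^(-1 / 5)
  }
  d <- density(theta_j, weights = w_j / sum(w_j), bw = h, n = 1024)
  d$x[which.max(d$y)]
}

#' Weighted mode estimator
#'
#' The mode of the inverse-variance weighted empirical density of the
#' per-variant ratio estimates (normal kernel, modified Silverman
#' bandwidth scaled by `phi`): consistent when the largest group of
#' variants sharing the same ratio is valid, even if they carry under half
#' the weight. Bootstrap SE as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier on the modified Silverman rule;
#'   default 1. Larger values smooth toward a single central mode.
#' @export
mr_weighted_mode <- function(data, phi = 1, n_boot = 1000L, seed = NULL) {
  assert_harmonized(data, min_snps = 3L, caller = "mr_weighted_mode")
  rc <- ratio_components(data)
  theta <- weighted_mode_point(rc$theta, rc$w, phi)
  boots <- with_seed_if(seed, boot_resample(data, n_boot, function(bx, by) {
    weighted_mode_point(by / bx, bx^2 / data$se_outcome^2, phi)
  }))
  se <- sd(boots)
  mr_result_row("weighted_mode", theta, se, z_to_p(theta / se), nrow(data))
}

#' Maximum-likelihood estimator
#'
#' Models each variant's observed exposure beta as normal around a latent
#' instrument effect and its outcome beta as normal around `theta` times
#' that effect, both with the reported standard errors. Profiling out the
#' latent effects leaves the one-dimensional objective
#' `sum((by - theta * bx)^2 / (se_y^2 + theta^2 se_x^2)) / 2`, maximized
#' numerically from the IVW starting value; the standard error comes from
#' the observed information of the profile likelihood. Unlike IVW this
#' accounts for uncertainty in the exposure associations.
#'
#' @inheritParams mr_ivw
#' @export
mr_max_likelihood <- function(data) {
  assert_harmonized(data, min_snps = 2L, caller = "mr_max_likelihood")
  bx <- data$beta_exposure
  by <- data$beta_outcome
  vx <- data$se_exposure^2
  vy <- data$se_outcome^2
  nll <- function(theta) sum((by - theta * bx)^2 / (vy + theta^2 * vx)) / 2
  start <- mr_ivw(data, mode = "fixed")$estimate
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-12))
  if (opt$convergence != 0) {
    abort(paste0("Maximum-likelihood optimization failed to converge: code ",
                 opt$convergence, "; ", opt$message %||% ""))
  }
  info <- opt$hessian[1, 1]
  if (!is.finite(info) || info <= 0) {
    abort("Maximum-likelihood observed information is not positive definite")
  }
  se <- sqrt(1 / info)
  theta <- opt$par
  mr_result_row("max_likelihood", theta, se, z_to_p(theta / se), nrow(data))
}

#' Multivariable MR (MVMR)
#'
#' Weighted least squares of the outcome betas on the matrix of exposure
#' betas without intercept, weights `1 / se_outcome^2`; each coefficient is
#' the direct effect of that exposure conditional on the others. Standard
#' errors carry a multiplicative overdispersion factor floored at 1, as in
#' [mr_ivw()].
#'
#' @param data Tibble with one row per shared variant: the outcome
#'   association and one beta column per exposure.
#' @param exposure_beta Character vector naming the exposure beta columns.
#' @param outcome_beta,outcome_se Column names of the outcome beta and SE;
#'   defaults `"beta_outcome"`, `"se_outcome"`.
#' @return A result tibble with one `mvmr` row per exposure (an `exposure`
#'   column carries the name). A zero column yields an `NA` estimate with
#'   a warning; duplicated or collinear non-zero columns raise an error
#'   naming the offending exposures.
#' @export
mr_mvmr <- function(data, exposure_beta, outcome_beta = "beta_outcome",
                    outcome_se = "se_outcome") {
  missing <- setdiff(c(exposure_beta, outcome_beta, outcome_se), names(data))
  if (length(missing) > 0) {
    abort(paste0("Columns not found: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[, exposure_beta, drop = FALSE])
  by <- data[[outcome_beta]]
  w <- 1 / data[[outcome_se]]^2
  k <- nrow(X)
  p <- ncol(X)
  if (k <= p) abort("MVMR needs more variants than exposures")

  fit <- lm(by ~ 0 + X, weights = w)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    offenders <- exposure_beta[aliased]
    nonzero <- vapply(offenders, function(cn) any(data[[cn]] != 0), logical(1))
    if (any(nonzero)) {
      abort(paste0(
        "Collinear exposure beta columns: ",
        paste(offenders[nonzero], collapse = ", ")
      ))
    }
    warn(paste0("All-zero exposure beta column(s) return NA estimates: ",
                paste(offenders, collapse = ", ")))
  }
  df <- k - sum(!aliased)
  rss <- sum(w * fit$residuals^2)
  sigma <- sqrt(rss / df)
  est <- rep(NA_real_, p)
  ses <- rep(NA_real_, p)
  est[!aliased] <- coef(fit)[!aliased]
  Xk <- X[, !aliased, drop = FALSE]
  vc <- solve(crossprod(Xk * sqrt(w)))
  ses[!aliased] <- sqrt(diag(vc)) * max(1, sigma)
  out <- purrr::map(seq_len(p), function(i) {
    if (is.na(est[i])) {
      mr_result_row("mvmr", NA_real_, NA_real_, NA_real_, k)
    } else {
      mr_result_row("mvmr", est[i], ses[i], z_to_p(est[i] / ses[i]), k, rss)
    }
  })
  dplyr::bind_cols(
    tibble::tibble(exposure = exposure_beta),
    dplyr::bind_rows(out)
  )
}

#' Run the full estimator suite on one harmonized set
#'
#' Applies IVW (the main analysis) plus the sensitivity estimators and
#' returns one tidy row per method. Methods whose minimum instrument count
#' is not met are silently skipped. For a binary outcome the estimates are
#' computed on the log-odds scale and additionally reported as odds ratios
#' with exp-transformed confidence bounds.
#'
#' @inheritParams mr_weighted_median
#' @param methods Methods to run; any of `"ivw"`, `"ivw_fe"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"max_likelihood"`.
#' @param outcome_type `"quantitative"` (default) or `"binary"`; binary
#'   adds `or`, `or_ci_lower`, `or_ci_upper` columns.
#' @return A result tibble with one row per method (two for Egger).
#' @export
mr_all <- function(data,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode", "max_likelihood"),
                   outcome_type = c("quantitative", "binary"),
                   n_boot = 1000L, seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  assert_harmonized(data, caller = "mr_all")
  k <- nrow(data)
  rows <- list()
  for (m in methods) {
    res <- switch(
      m,
      ivw = if (k >= 2) mr_ivw(data),
      ivw_fe = if (k >= 2) mr_ivw(data, mode = "fixed"),
      egger = if (k >= 3) mr_egger(data),
      weighted_median = if (k >= 3) {
        mr_weighted_median(data, n_boot = n_boot, seed = seed)
      },
      weighted_mode = if (k >= 3) {
        mr_weighted_mode(data, n_boot = n_boot, seed = seed)
      },
      max_likelihood = if (k >= 2) mr_max_likelihood(data),
      abort(paste0("Unknown method: ", m))
    )
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (outcome_type == "binary" && nrow(out) > 0) {
    out <- dplyr::mutate(
      out,
      or = ifelse(.data$method == "egger_intercept", NA_real_,
                  exp(.data$estimate)),
      or_ci_lower = ifelse(.data$method == "egger_intercept", NA_real_,
                           exp(.data$ci_lower)),
      or_ci_upper = ifelse(.data$method == "egger_intercept", NA_real_,
                           exp(.data$ci_upper))
    )
  }
  out
}
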