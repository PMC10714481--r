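#' Cochran Q heterogeneity statistic
#'
#' `Q = sum_j w_j (theta_j - theta)^2` over the per-variant ratio
#' estimates, with inverse first-order delta variances as weights and the
#' IVW estimate as the reference by default; the p-value uses the
#' chi-square reference with `k - 1` degrees of freedom. Excess Q signals
#' heterogeneity of the variant-level causal estimates (invalid
#' instruments or pleiotropy).
#'
#' @inheritParams mr_ivw
#' @param theta Reference causal estimate; default the IVW estimate from
#'   `data`.
#' @return A one-row tibble with `Q`, `df`, `p_value`.
#' @export
cochran_q <- function(data, theta = NULL) {
  assert_harmonized(data, min_snps = 2L, caller = "cochran_q")
  if (is.null(theta)) theta <- mr_ivw(data, mode = "fixed")$estimate
  rc <- ratio_components(data)
  Q <- sum(rc$w * (rc$theta - theta)^2)
  df <- nrow(data) - 1L
  tibble::tibble(Q = Q, df = df, p_value = pchisq(Q, df, lower.tail = FALSE))
}

#' Combined heterogeneity and pleiotropy report
#'
#' One row per harmonized set: the Cochran Q test against the IVW estimate
#' and the MR-Egger intercept test for directional pleiotropy (intercept
#' columns are `NA` when fewer than 3 instruments are available).
#'
#' @inheritParams mr_ivw
#' @return A one-row tibble with `Q`, `df`, `q_p_value`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_diagnostics <- function(data) {
  q <- cochran_q(data)
  if (nrow(data) >= 3) {
    eg <- mr_egger(data)
    ic <- eg[eg$method == "egger_intercept", ]
    tibble::tibble(
      Q = q$Q, df = q$df, q_p_value = q$p_value,
      egger_intercept = ic$estimate,
      egger_intercept_se = ic$se,
      egger_intercept_p = ic$p_value
    )
  } else {
    tibble::tibble(
      Q = q$Q, df = q$df, q_p_value = q$p_value,
      egger_intercept = NA_real_,
      egger_intercept_se = NA_real_,
      egger_intercept_p = NA_real_
    )
  }
}

#' Leave-one-out analysis
#'
#' Refits the IVW estimator k times, omitting one variant each time, to
#' find variants that drive the pooled estimate. A variant is flagged when
#' its omission flips significance at `alpha` or moves the estimate by
#' more than one full-set pooled standard error.
#'
#' @inheritParams mr_ivw
#' @param alpha Significance level for the flip criterion; default 0.05.
#' @return A tibble with one row per omitted variant: `snp_omitted`, the
#'   IVW columns, and `flagged`.
#' @export
mr_leave_one_out <- function(data, mode = "multiplicative_random",
                             alpha = 0.05) {
  assert_harmonized(data, min_snps = 3L, caller = "mr_leave_one_out")
  full <- mr_ivw(data, mode = mode)
  ids <- if ("snp" %in% names(data)) data$snp else as.character(seq_len(nrow(data)))
  rows <- purrr::map(seq_len(nrow(data)), function(j) {
    fit <- mr_ivw(data[-j, , drop = FALSE], mode = mode)
    fit$snp_omitted <- ids[j]
    fit
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- (out$p_value < alpha) != (full$p_value < alpha) |
    abs(out$estimate - full$estimate) > full$se
  dplyr::relocate(out, "snp_omitted")
}

#' Approximate statistical power of a two-sample MR analysis
#'
#' Non-centrality-based approximation for unit-variance traits: the power
#' of the two-sided level-`alpha` Wald test is
#' `pnorm(-z_{1-alpha/2} + |theta| sqrt(n R2 v))` with `v = 1` for a
#' continuous outcome and `v = case_fraction (1 - case_fraction)` for a
#' binary (log-odds `theta`) outcome, `n` the outcome sample size and `R2`
#' the exposure variance explained by the instruments.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param R2 Instrument variance explained, in `[0, 1)`.
#' @param theta_true True causal effect (per SD exposure; log-odds for a
#'   binary outcome).
#' @param alpha Two-sided test level; default 0.05.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction Case proportion, required for binary outcomes.
#' @return Power in `[0, 1]`.
#' @export
mr_power <- function(n_outcome, R2, theta_true, alpha = 0.05,
                     outcome_type = c("continuous", "binary"),
                     case_fraction = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (any(R2 < 0) || any(R2 >= 1)) abort("R2 must lie in [0, 1)")
  v <- if (outcome_type == "continuous") {
    1
  } else {
    if (is.null(case_fraction) || any(case_fraction <= 0) ||
        any(case_fraction >= 1)) {
      abort("Binary outcomes need case_fraction in (0, 1)")
    }
    case_fraction * (1 - case_fraction)
  }
  ncp <- abs(theta_true) * sqrt(n_outcome * R2 * v)
  pnorm(-qnorm(1 - alpha / 2) + ncp)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values in the input order, with enforced
#' monotonicity and `q <= 1`. The testing family (for this package:
#' typically the drug targets tested against one outcome dataset) is
#' whatever vector the caller passes — family membership is explicit
#' configuration, never implicit.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values, `q >= p` elementwise, mapped back to input
#'   positions.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Combine estimates of one trait across consortia
#'
#' Inverse-variance fixed-effect pooling, or DerSimonian-Laird random
#' effects when between-study heterogeneity demands it. Under
#' `rule = "auto"` the random-effects model is selected when the
#' across-study Q test has `p < het_p_threshold` (default 0.10).
#' Computation is delegated to [metafor::rma()] (`method = "FE"` / `"DL"`).
#'
#' @param data Tibble with columns `estimate` and `se`, one row per study.
#' @param rule `"auto"` (default), `"fixed"`, or `"random"`.
#' @param het_p_threshold Heterogeneity p below which `"auto"` switches to
#'   random effects; default 0.10.
#' @return A one-row tibble: `model`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`, `tau2`, `Q_meta`, `p_het`, `n_studies`. With a
#'   single study the input passes through with a warning.
#' @export
meta_combine <- function(data, rule = c("auto", "fixed", "random"),
                         het_p_threshold = 0.10) {
  rule <- match.arg(rule)
  if (!all(c("estimate", "se") %in% names(data))) {
    abort("meta_combine needs estimate and se columns")
  }
  if (any(data$se <= 0)) abort("Standard errors must be positive")
  if (nrow(data) < 2) {
    warn("Fewer than 2 estimates; passing the input through unpooled")
    ci <- ci_bounds(data$estimate, data$se)
    return(tibble::tibble(
      model = "none", estimate = data$estimate, se = data$se,
      ci_lower = ci$lower, ci_upper = ci$upper,
      p_value = z_to_p(data$estimate / data$se),
      tau2 = 0, Q_meta = NA_real_, p_het = NA_real_,
      n_studies = nrow(data)
    ))
  }
  fe <- metafor::rma(yi = data$estimate, sei = data$se, method = "FE")
  model <- switch(rule,
    fixed = "fixed",
    random = "random",
    auto = if (fe$QEp < het_p_threshold) "random" else "fixed"
  )
  fit <- if (model == "random") {
    metafor::rma(yi = data$estimate, sei = data$se, method = "DL")
  } else {
    fe
  }
  tibble::tibble(
    model = model,
    estimate = as.numeric(fit$beta),
    se = fit$se,
    ci_lower = fit$ci.lb,
    ci_upper = fit$ci.ub,
    p_value = fit$pval,
    tau2 = if (model == "random") fit$tau2 else 0,
    Q_meta = fe$QE,
    p_het = fe$QEp,
    n_studies = nrow(data)
  )
}
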