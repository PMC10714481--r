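#' Two-step MR mediation decomposition
#'
#' Decomposes a total causal effect of an exposure on the outcome into the
#' part transmitted through a mediator and the remainder. With `beta_a`
#' the exposure-to-mediator estimate, `beta_b` the mediator-to-outcome
#' estimate adjusted for the exposure, and `beta_c` the total effect:
#' indirect effect `= beta_a * beta_b`, direct effect
#' `= beta_c - beta_a * beta_b` (the decomposition identity
#' direct + indirect = total holds exactly by construction), and
#' proportion mediated `= indirect / beta_c`, reported as a percentage.
#' The indirect-effect SE uses the product delta method
#' `sqrt(beta_a^2 se_b^2 + beta_b^2 se_a^2)`; the proportion SE propagates
#' `se_c` by the ratio delta method. A binary mediator's effects are
#' carried on the log-odds scale throughout the product, which is an
#' approximation.
#'
#' @param beta_a,se_a Exposure-to-mediator estimate and SE.
#' @param beta_b,se_b Adjusted mediator-to-outcome estimate and SE.
#' @param beta_c,se_c Total exposure-to-outcome estimate and SE. `se_a`,
#'   `se_b`, `se_c` may be `NA` when only the point decomposition is
#'   needed.
#' @return A one-row tibble: `beta_a`, `beta_b`, `beta_c`, `indirect`,
#'   `se_indirect`, `direct` (`beta_c_prime`), `proportion_mediated_pct`,
#'   `se_proportion_pct`, 95% CIs, and `total_ci_spans_zero` flagging when
#'   the total effect's own CI includes 0 (the proportion is then
#'   unstable).
#' @export
#' @examples
#' # total 0.164 and direct 0.127 imply indirect 0.037, ~22.6% mediated
#' two_step_mediation(0.5, 0.1, 0.074, 0.02, 0.164, 0.026)
two_step_mediation <- function(beta_a, se_a = NA_real_,
                               beta_b, se_b = NA_real_,
                               beta_c, se_c = NA_real_) {
  if (beta_c == 0) {
    abort("Proportion mediated undefined for a zero total effect")
  }
  indirect <- beta_a * beta_b
  direct <- beta_c - indirect
  se_indirect <- sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)
  prop <- indirect / beta_c
  # delta method on the ratio indirect / total (independent numerators)
  se_prop <- sqrt(se_indirect^2 / beta_c^2 +
                    indirect^2 * se_c^2 / beta_c^4)
  ci_ind <- ci_bounds(indirect, se_indirect)
  ci_prop <- ci_bounds(prop, se_prop)
  spans_zero <- if (is.finite(se_c)) {
    ci <- ci_bounds(beta_c, se_c)
    ci$lower <= 0 && ci$upper >= 0
  } else {
    NA
  }
  tibble::tibble(
    beta_a = beta_a, se_a = se_a,
    beta_b = beta_b, se_b = se_b,
    beta_c = beta_c, se_c = se_c,
    indirect = indirect,
    se_indirect = se_indirect,
    indirect_ci_lower = ci_ind$lower,
    indirect_ci_upper = ci_ind$upper,
    direct = direct,
    proportion_mediated_pct = 100 * prop,
    se_proportion_pct = 100 * se_prop,
    proportion_ci_lower_pct = 100 * ci_prop$lower,
    proportion_ci_upper_pct = 100 * ci_prop$upper,
    total_ci_spans_zero = spans_zero
  )
}

#' Decomposition from printed total and direct effects
#'
#' Convenience inversion of the two-step identity for reported results:
#' given a total effect and the direct effect that remains after adjusting
#' for the mediator, the indirect effect is their difference and the
#' proportion mediated is `indirect / total`, as a percentage.
#'
#' @param total,direct Total and direct effect estimates.
#' @return A one-row tibble with `total`, `direct`, `indirect`,
#'   `proportion_mediated_pct`.
#' @export
#' @examples
#' mediation_from_total_direct(0.164, 0.127)
mediation_from_total_direct <- function(total, direct) {
  if (total == 0) abort("Proportion mediated undefined for a zero total effect")
  indirect <- total - direct
  tibble::tibble(
    total = total, direct = direct, indirect = indirect,
    proportion_mediated_pct = 100 * indirect / total
  )
}

#' Run the full two-step mediation pipeline on summary tables
#'
#' Orchestrates the three MR fits behind a mediation decomposition:
#' (1) exposure-to-mediator IVW on the exposure's cis instruments;
#' (2) mediator-to-outcome effect adjusted for the exposure, by
#' multivariable MR of the outcome betas on the mediator and exposure
#' betas over the union of both instrument sets (an unadjusted IVW option
#' exists); (3) total exposure-to-outcome IVW; then [two_step_mediation()].
#'
#' @param exposure,mediator,outcome Summary-statistic tibbles in the
#'   standard vocabulary, all sharing snp ids where relevant.
#' @param target Optional gene window (see [gene_targets()]); when given,
#'   exposure instruments are cis-selected around it, otherwise genome-wide.
#' @param ld Optional LD r-squared matrix for clumping.
#' @param p_threshold,r2_threshold,flank_bp Instrument-selection settings;
#'   see [select_cis_instruments()].
#' @param adjusted Use MVMR exposure adjustment in step two (default
#'   `TRUE`); `FALSE` uses plain IVW of the outcome on mediator
#'   instruments.
#' @param steiger Apply Steiger filtering to each instrument set; default
#'   `TRUE`.
#' @return A list with `decomposition` (the [two_step_mediation()] row)
#'   and `stages` (named list of the three stage estimates plus instrument
#'   counts).
#' @export
run_mediation_pipeline <- function(exposure, mediator, outcome,
                                   target = NULL, ld = NULL,
                                   p_threshold = 5e-8, r2_threshold = 0.3,
                                   flank_bp = 100000L, adjusted = TRUE,
                                   steiger = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Mediation stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  x_instruments <- stage("exposure instrument selection", {
    if (is.null(target)) {
      suppressWarnings(select_instruments(exposure, ld = ld,
                                          p_threshold = p_threshold,
                                          r2_threshold = r2_threshold))
    } else {
      suppressWarnings(select_cis_instruments(exposure, target, ld = ld,
                                              p_threshold = p_threshold,
                                              r2_threshold = r2_threshold,
                                              flank_bp = flank_bp))
    }
  })
  if (nrow(x_instruments) < 2) {
    abort("Mediation stage 'exposure instrument selection' failed: fewer than 2 exposure instruments")
  }
  m_instruments <- stage("mediator instrument selection", {
    suppressWarnings(select_instruments(mediator, ld = ld,
                                        p_threshold = p_threshold,
                                        r2_threshold = r2_threshold))
  })
  if (nrow(m_instruments) < 2) {
    abort("Mediation stage 'step two infeasible' failed: fewer than 2 mediator instruments survive selection")
  }

  prep <- function(instruments, out_tbl, name) {
    h <- stage(name, harmonize(dplyr::select(instruments, -"clump_order"),
                               out_tbl))
    if (steiger && all(c("n_exposure", "n_outcome") %in% names(h)) &&
        !anyNA(h$n_exposure) && !anyNA(h$n_outcome)) {
      h <- steiger_filter(h)
    }
    h
  }

  h_xm <- prep(x_instruments, mediator, "harmonize exposure-mediator")
  step1 <- mr_ivw(h_xm)

  h_xy <- prep(x_instruments, outcome, "harmonize exposure-outcome")
  total <- mr_ivw(h_xy)

  step2 <- if (adjusted) {
    # exposure betas for the union of both instrument sets come from the
    # exposure GWAS itself, so the two MVMR columns are per-trait, per-SNP
    union_snps <- union(x_instruments$snp, m_instruments$snp)
    exposure_union <- dplyr::filter(exposure, .data$snp %in% union_snps)
    h_union_y <- stage("harmonize union-outcome",
                       harmonize(exposure_union, outcome))
    med_lookup <- setNames(mediator$beta, mediator$snp)
    med_ea <- setNames(mediator$effect_allele, mediator$snp)
    h_union_y$beta_mediator <- ifelse(
      med_ea[h_union_y$snp] == h_union_y$effect_allele,
      med_lookup[h_union_y$snp], -med_lookup[h_union_y$snp]
    )
    h_union_y <- h_union_y[is.finite(h_union_y$beta_mediator), , drop = FALSE]
    fit <- stage("step two MVMR", mr_mvmr(
      h_union_y, exposure_beta = c("beta_mediator", "beta_exposure")
    ))
    fit[fit$exposure == "beta_mediator", setdiff(names(fit), "exposure")]
  } else {
    h_my <- prep(m_instruments, outcome, "harmonize mediator-outcome")
    mr_ivw(h_my)
  }

  decomposition <- two_step_mediation(
    beta_a = step1$estimate, se_a = step1$se,
    beta_b = step2$estimate, se_b = step2$se,
    beta_c = total$estimate, se_c = total$se
  )
  list(
    decomposition = decomposition,
    stages = list(
      exposure_to_mediator = step1,
      mediator_to_outcome_adjusted = step2,
      total = total,
      n_exposure_instruments = nrow(x_instruments),
      n_mediator_instruments = nrow(m_instruments)
    )
  )
}
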