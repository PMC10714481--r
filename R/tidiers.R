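#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a drug-target scan into one row per gene and method
#'
#' @param x An `mr_target_scan` from [run_drug_target_mr()].
#' @param ... Unused.
#' @return The estimates tibble (gene x method rows).
#' @export
tidy.mr_target_scan <- function(x, ...) x$estimates

#' One-row-per-target summary of a drug-target scan
#'
#' The main (IVW) estimate joined with instrument strength and the
#' heterogeneity/pleiotropy diagnostics.
#'
#' @inheritParams tidy.mr_target_scan
#' @export
glance.mr_target_scan <- function(x, ...) {
  ivw <- dplyr::filter(x$estimates, .data$method == "ivw_mre")
  out <- dplyr::left_join(
    ivw,
    dplyr::select(x$strength, "gene", "R2", "F", "weak"),
    by = "gene"
  )
  dplyr::left_join(
    out,
    dplyr::select(x$diagnostics, "gene", "Q", "q_p_value",
                  "egger_intercept", "egger_intercept_p"),
    by = "gene"
  )
}

#' Forest plot of a drug-target scan
#'
#' One row per gene: the main (IVW) estimate with its 95% interval, on
#' the odds-ratio scale for binary outcomes.
#'
#' @param object An `mr_target_scan`.
#' @param method Which method's rows to draw; default `"ivw_mre"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_target_scan <- function(object, method = "ivw_mre", ...) {
  d <- dplyr::filter(object$estimates, .data$method == !!method)
  binary <- object$config$outcome_type == "binary"
  if (binary) {
    d <- dplyr::mutate(d, est = .data$or, lo = .data$or_ci_lower,
                       hi = .data$or_ci_upper)
    null_line <- 1
    xlab <- "Odds ratio (95% CI) per unit lipid lowering"
  } else {
    d <- dplyr::mutate(d, est = .data$estimate, lo = .data$ci_lower,
                       hi = .data$ci_upper)
    null_line <- 0
    xlab <- "Beta (95% CI) per unit lipid lowering"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$est,
                                  y = stats::reorder(.data$gene, .data$est))) +
    ggplot2::geom_vline(xintercept = null_line, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a harmonized instrument set with fitted slopes
#'
#' Outcome betas against exposure betas with error bars and the IVW and
#' MR-Egger fitted lines: the workhorse visual check for pleiotropy.
#'
#' @param data Harmonized tibble (see [harmonize()]).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(data) {
  assert_harmonized(data, caller = "plot_mr_scatter")
  ivw <- mr_ivw(data)
  layers <- list(
    ggplot2::geom_abline(slope = ivw$estimate, intercept = 0,
                         colour = "steelblue")
  )
  if (nrow(data) >= 3) {
    eg <- mr_egger(data)
    layers <- c(layers, list(ggplot2::geom_abline(
      slope = eg$estimate[eg$method == "egger"],
      intercept = eg$estimate[eg$method == "egger_intercept"],
      colour = "firebrick", linetype = "dashed"
    )))
  }
  ggplot2::ggplot(data, ggplot2::aes(.data$beta_exposure,
                                     .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - 1.96 * .data$se_outcome,
      ymax = .data$beta_outcome + 1.96 * .data$se_outcome
    ), width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - 1.96 * .data$se_exposure,
      xmax = .data$beta_exposure + 1.96 * .data$se_exposure
    ), height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    layers +
    ggplot2::labs(x = "Variant effect on exposure",
                  y = "Variant effect on outcome") +
    ggplot2::theme_minimal()
}

#' Leave-one-out forest plot
#'
#' @param loo Result of [mr_leave_one_out()].
#' @return A ggplot object with flagged variants highlighted.
#' @export
plot_leave_one_out <- function(loo) {
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$estimate,
                                    y = .data$snp_omitted,
                                    colour = .data$flagged)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "IVW estimate omitting this variant", y = NULL) +
    ggplot2::theme_minimal()
}
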