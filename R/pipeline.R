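# flip a results table from per-unit-raising to per-unit-lowering coding
orient_lowering <- function(res) {
  if (nrow(res) == 0) return(res)
  res$estimate <- -res$estimate
  lower <- res$ci_lower
  res$ci_lower <- -res$ci_upper
  res$ci_upper <- -lower
  if ("or" %in% names(res)) {
    res$or <- exp(res$estimate)
    res$or_ci_lower <- exp(res$ci_lower)
    res$or_ci_upper <- exp(res$ci_upper)
  }
  res
}

#' Drug-target MR across a panel of gene targets
#'
#' Runs the full per-target pipeline: cis-instrument selection around each
#' gene window, allele harmonization against the outcome, Steiger
#' directionality filtering, instrument-strength F statistics, the
#' estimator suite with heterogeneity/pleiotropy diagnostics and
#' leave-one-out, an LD-threshold sensitivity grid, and
#' Benjamini-Hochberg adjustment of the main (IVW) p-values across the
#' targets analyzed against this outcome. Per-target failures are
#' isolated: the run completes and the failure is recorded in the status
#' table.
#'
#' Sign convention: estimates are reported per unit of lipid LOWERING
#' (mimicking the drug effect), i.e. the per-unit-increase estimate is
#' negated, so a positive lifespan estimate reads "lowering the lipid
#' extends lifespan". Set `effect_direction = "raising"` for the raw
#' per-SD-increase coding. Because every estimator is equivariant under
#' jointly recoding alleles, flipping the allele coding of the exposure
#' file leaves all conclusions unchanged.
#'
#' @param exposure,outcome Summary-statistic tibbles (standard
#'   vocabulary).
#' @param targets Gene-window tibble (see [gene_targets()]); rows with an
#'   `eligible` column set to `FALSE` are skipped with a status entry.
#' @param ld Optional LD r-squared matrix.
#' @param outcome_type `"quantitative"` or `"binary"` (odds-ratio
#'   reporting).
#' @param effect_direction `"lowering"` (default) or `"raising"`.
#' @param p_threshold,r2_threshold,flank_bp,min_snps Instrument selection
#'   settings (see [select_cis_instruments()]).
#' @param r2_grid LD thresholds for the sensitivity reanalysis; default
#'   `c(0.3, 0.1, 0.01, 0.001)`.
#' @param steiger Apply Steiger filtering; default `TRUE` (needs n
#'   columns in both tables).
#' @param n_boot,seed Bootstrap settings passed to the median/mode
#'   estimators.
#' @return An object of class `mr_target_scan`: a list with `estimates`
#'   (per gene x method, with `q_value` on the IVW rows), `instruments`,
#'   `strength`, `diagnostics`, `leave_one_out`, `sensitivity`, `status`,
#'   and `config`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
run_drug_target_mr <- function(exposure, outcome, targets, ld = NULL,
                               outcome_type = c("quantitative", "binary"),
                               effect_direction = c("lowering", "raising"),
                               p_threshold = 5e-8, r2_threshold = 0.3,
                               flank_bp = 100000L, min_snps = 2L,
                               r2_grid = c(0.3, 0.1, 0.01, 0.001),
                               steiger = TRUE, n_boot = 1000L,
                               seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  effect_direction <- match.arg(effect_direction)

  estimates <- list()
  instruments <- list()
  strength <- list()
  diagnostics <- list()
  loo <- list()
  sensitivity <- list()
  status <- list()

  for (i in seq_len(nrow(targets))) {
    target <- targets[i, ]
    gene <- target$gene
    rec <- function(n_instr, state, message = NA_character_) {
      tibble::tibble(gene = gene, n_instruments = n_instr,
                     status = state, message = message)
    }
    if ("eligible" %in% names(target) && !isTRUE(target$eligible)) {
      status[[gene]] <- rec(0L, "skipped_ineligible")
      next
    }
    res <- tryCatch({
      sel <- suppressWarnings(select_cis_instruments(
        exposure, target, ld = ld, flank_bp = flank_bp,
        p_threshold = p_threshold, r2_threshold = r2_threshold,
        min_snps = min_snps
      ))
      if (isTRUE(attr(sel, "insufficient"))) {
        status[[gene]] <- rec(nrow(sel), "insufficient_ivs")
        NULL
      } else {
        h <- harmonize(dplyr::select(sel, -"clump_order"), outcome)
        n_pre <- nrow(h)
        if (steiger && all(c("n_exposure", "n_outcome") %in% names(h)) &&
            !anyNA(h$n_exposure) && !anyNA(h$n_outcome)) {
          h <- steiger_filter(h)
        }
        if (nrow(h) < min_snps) {
          status[[gene]] <- rec(nrow(h), "insufficient_after_filtering")
          NULL
        } else {
          list(sel = sel, h = h, n_pre = n_pre)
        }
      }
    }, error = function(e) {
      status[[gene]] <<- rec(NA_integer_, "failed", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    h <- res$h

    est <- mr_all(h, outcome_type = outcome_type, n_boot = n_boot,
                  seed = seed)
    if (effect_direction == "lowering") est <- orient_lowering(est)
    est <- dplyr::bind_cols(tibble::tibble(gene = gene), est)
    estimates[[gene]] <- est

    instruments[[gene]] <- dplyr::bind_cols(
      tibble::tibble(gene = gene), res$sel
    )
    strength[[gene]] <- dplyr::bind_cols(
      tibble::tibble(gene = gene), instrument_strength(h)
    )
    diagnostics[[gene]] <- dplyr::bind_cols(
      tibble::tibble(gene = gene), mr_diagnostics(h)
    )
    if (nrow(h) >= 3) {
      l <- mr_leave_one_out(h)
      if (effect_direction == "lowering") l <- orient_lowering(l)
      loo[[gene]] <- dplyr::bind_cols(tibble::tibble(gene = gene), l)
    }

    sens <- purrr::map(r2_grid, function(r2) {
      tryCatch({
        sel_r2 <- suppressWarnings(select_cis_instruments(
          exposure, target, ld = ld, flank_bp = flank_bp,
          p_threshold = p_threshold, r2_threshold = r2,
          min_snps = min_snps
        ))
        if (isTRUE(attr(sel_r2, "insufficient"))) return(NULL)
        h_r2 <- harmonize(dplyr::select(sel_r2, -"clump_order"), outcome)
        if (nrow(h_r2) < 2) return(NULL)
        fit <- mr_ivw(h_r2)
        if (effect_direction == "lowering") fit <- orient_lowering(fit)
        dplyr::bind_cols(
          tibble::tibble(gene = gene, r2_threshold = r2), fit
        )
      }, error = function(e) NULL)
    })
    sensitivity[[gene]] <- dplyr::bind_rows(sens)
    status[[gene]] <- rec(nrow(h), "ok",
                          sprintf("%d instrument(s) removed by Steiger",
                                  res$n_pre - nrow(h)))
  }

  estimates <- dplyr::bind_rows(estimates)
  if (nrow(estimates) > 0) {
    # FDR family: the analyzed targets' main IVW tests against this outcome
    ivw <- estimates$method == "ivw_mre"
    estimates$q_value <- NA_real_
    estimates$q_value[ivw] <- bh_fdr(estimates$p_value[ivw])
  }

  out <- list(
    estimates = estimates,
    instruments = dplyr::bind_rows(instruments),
    strength = dplyr::bind_rows(strength),
    diagnostics = dplyr::bind_rows(diagnostics),
    leave_one_out = dplyr::bind_rows(loo),
    sensitivity = dplyr::bind_rows(sensitivity),
    status = dplyr::bind_rows(status),
    config = list(
      outcome_type = outcome_type, effect_direction = effect_direction,
      p_threshold = p_threshold, r2_threshold = r2_threshold,
      flank_bp = flank_bp, min_snps = min_snps, r2_grid = r2_grid,
      steiger = steiger, n_boot = n_boot, seed = seed
    )
  )
  class(out) <- "mr_target_scan"
  out
}

#' Positive-control analysis against an outcome with known direction
#'
#' Points the drug-target machinery at a control outcome whose expected
#' effect direction is established (for lipid lowering: protective
#' against coronary disease and diabetes) and annotates each target's
#' main estimate with whether its direction matches expectation.
#'
#' @inheritParams run_drug_target_mr
#' @param expected_direction `"protective"` (lowering reduces risk,
#'   estimate < 0 / OR < 1 under the lowering convention) or
#'   `"harmful"`.
#' @return An `mr_target_scan` whose `estimates` IVW rows carry
#'   `direction_consistent`.
#' @export
run_positive_control <- function(exposure, outcome, targets, ld = NULL,
                                 outcome_type = "binary",
                                 expected_direction = c("protective",
                                                        "harmful"),
                                 ...) {
  expected_direction <- match.arg(expected_direction)
  scan <- run_drug_target_mr(exposure, outcome, targets, ld = ld,
                             outcome_type = outcome_type, ...)
  if (nrow(scan$estimates) > 0) {
    expected_sign <- if (expected_direction == "protective") -1 else 1
    ivw <- scan$estimates$method == "ivw_mre"
    scan$estimates$direction_consistent <- NA
    scan$estimates$direction_consistent[ivw] <-
      sign(scan$estimates$estimate[ivw]) == expected_sign
  }
  scan$config$expected_direction <- expected_direction
  scan
}

#' Write a drug-target scan as a report directory
#'
#' Estimates, instruments, strength, diagnostics, leave-one-out and
#' sensitivity tables as TSV plus a JSON manifest capturing the
#' configuration, seeds, status of every target and package version, so
#' every number in the report is traceable.
#'
#' @param scan An `mr_target_scan`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(scan, dir) {
  stopifnot(inherits(scan, "mr_target_scan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("estimates", "instruments", "strength", "diagnostics",
              "leave_one_out", "sensitivity", "status")
  for (nm in tables) {
    tbl <- scan[[nm]]
    if (!is.null(tbl) && nrow(tbl) > 0) {
      tbl <- dplyr::select(tbl, -dplyr::where(is.list))
      readr::write_tsv(tbl, file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  manifest <- list(
    package = "targetmr",
    version = as.character(utils::packageVersion("targetmr")),
    config = scan$config,
    targets_analyzed = unique(scan$estimates$gene),
    status = scan$status
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.mr_target_scan <- function(x, ...) {
  cat("<mr_target_scan>\n")
  cat(sprintf("  targets analyzed: %d (of %d attempted)\n",
              length(unique(x$estimates$gene)), nrow(x$status)))
  cat(sprintf("  outcome type: %s; effect direction: per unit lipid %s\n",
              x$config$outcome_type, x$config$effect_direction))
  if (nrow(x$estimates) > 0) {
    ivw <- x$estimates[x$estimates$method == "ivw_mre", ]
    cat("  main (IVW) estimates:\n")
    print(ivw[, intersect(c("gene", "estimate", "ci_lower", "ci_upper",
                            "p_value", "q_value", "n_snp"), names(ivw))])
  }
  invisible(x)
}
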