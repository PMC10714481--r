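#' Wakefield log approximate Bayes factor
#'
#' For one variant with estimated effect `beta` and standard error `se`,
#' and a normal prior with variance `W` on the true effect under the
#' alternative, the approximate Bayes factor in favor of association is
#' `ABF` with `log ABF = 0.5 (log(V / (V + W)) + z^2 W / (V + W))`,
#' `V = se^2`, `z = beta / se`. Vectorized over variants.
#'
#' @param beta,se Effect estimate(s) and standard error(s), `se > 0`.
#' @param W Prior variance of the true effect under the alternative;
#'   conventional defaults are `0.15^2` for a quantitative trait and
#'   `0.2^2` on the log-odds scale for a binary trait.
#' @return Log approximate Bayes factor(s).
#' @export
wakefield_abf <- function(beta, se, W) {
  if (any(se <= 0)) abort("se must be positive")
  if (any(W <= 0)) abort("Prior variance W must be positive")
  V <- se^2
  z <- beta / se
  0.5 * (log(V / (V + W)) + z^2 * W / (V + W))
}

#' Bayesian colocalization over a cis region
#'
#' Tests whether two traits share a single causal variant in a region,
#' under the one-causal-variant-per-trait assumption. Per-variant log
#' approximate Bayes factors ([wakefield_abf()]) for each trait are
#' combined into the evidence for five hypotheses — H0 no association,
#' H1/H2 association with one trait only, H3 two distinct causal
#' variants, H4 one shared causal variant — weighted by the per-variant
#' prior probabilities `p1`, `p2` and the shared prior `p12`, and
#' normalized into posterior probabilities. All accumulation is done in
#' log space with log-sum-exp so large regions cannot underflow. A
#' posterior `PP.H4` above `h4_threshold` is flagged as strong
#' colocalization.
#'
#' @param region1,region2 Summary-statistic tibbles over the same region
#'   (standard vocabulary; joined on `snp`, at least 2 shared variants).
#' @param p1,p2 Prior probability a variant is causal for trait 1 / 2
#'   only; defaults `1e-4`.
#' @param p12 Prior probability a variant is causal for both; default
#'   `1e-5`.
#' @param W1,W2 Prior effect variances per trait; defaults `0.15^2`
#'   (quantitative). Use `0.2^2` for a binary trait's log-odds.
#' @param h4_threshold Decision threshold for strong colocalization;
#'   default 0.85.
#' @return A one-row tibble with `pp_h0` ... `pp_h4` (summing to 1),
#'   `n_snps`, `strong_coloc`, and the priors; the per-variant log ABF
#'   table is attached as attribute `"abf_table"`.
#' @export
coloc_abf <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W1 = 0.15^2, W2 = 0.15^2, h4_threshold = 0.85) {
  shared <- dplyr::inner_join(
    dplyr::select(region1, "snp", beta1 = "beta", se1 = "se"),
    dplyr::select(region2, "snp", beta2 = "beta", se2 = "se"),
    by = "snp"
  )
  if (nrow(shared) < 2) {
    abort("Colocalization needs at least 2 shared variants in the region")
  }
  l1 <- wakefield_abf(shared$beta1, shared$se1, W1)
  l2 <- wakefield_abf(shared$beta2, shared$se2, W2)

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)

  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)

  out <- tibble::tibble(
    pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
    pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
    n_snps = nrow(shared),
    strong_coloc = pp[["h4"]] > h4_threshold,
    p1 = p1, p2 = p2, p12 = p12
  )
  attr(out, "abf_table") <- tibble::tibble(
    snp = shared$snp, labf_trait1 = l1, labf_trait2 = l2
  )
  out
}

#' Write a colocalization report
#'
#' The five posteriors, priors and decision flag as JSON, and optionally
#' the per-variant log approximate Bayes factors as TSV.
#'
#' @param x Result of [coloc_abf()].
#' @param path JSON output path.
#' @param abf_path Optional TSV path for the per-variant log ABF table.
#' @return `path`, invisibly.
#' @export
write_coloc_report <- function(x, path, abf_path = NULL) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(abf_path)) {
    readr::write_tsv(attr(x, "abf_table"), abf_path, progress = FALSE)
  }
  invisible(path)
}

#' Select expression (eQTL) instruments for a gene
#'
#' Instruments for gene expression are restricted to the wide cis window
#' (default +/-1 Mb of the gene), filtered to common variants
#' (`MAF = min(eaf, 1 - eaf) > maf_min`) whose Benjamini-Hochberg adjusted
#' association q-values fall under `fdr_max`, then clumped at the
#' drug-target LD threshold. The FDR family is the set of variants passing
#' the window and MAF filters for this gene.
#'
#' @inheritParams select_cis_instruments
#' @param flank_bp Cis window flank; default 1,000,000.
#' @param maf_min Minor-allele-frequency floor; default 0.01.
#' @param fdr_max BH-adjusted q-value ceiling; default 0.05.
#' @return Selected instruments (tibble with `clump_order`), flagged
#'   `"insufficient"` as in [select_cis_instruments()].
#' @export
select_eqtl_instruments <- function(data, target, ld = NULL,
                                    flank_bp = 1000000L, maf_min = 0.01,
                                    fdr_max = 0.05, r2_threshold = 0.3,
                                    min_snps = 2L) {
  needed <- c("chrom", "pos", "eaf", "pvalue")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("eQTL instrument selection needs columns: ",
                 paste(missing, collapse = ", ")))
  }
  window <- dplyr::filter(
    data,
    .data$chrom == as.character(target$chrom),
    .data$pos >= target$start - flank_bp,
    .data$pos <= target$end + flank_bp,
    pmin(.data$eaf, 1 - .data$eaf) > maf_min
  )
  if (nrow(window) == 0) {
    warn(sprintf("No common variant in the %s eQTL window", target$gene))
    out <- dplyr::mutate(window, clump_order = integer(0))
    attr(out, "insufficient") <- TRUE
    attr(out, "gene") <- target$gene
    return(out)
  }
  window$qvalue <- bh_fdr(window$pvalue)
  passing <- dplyr::filter(window, .data$qvalue < fdr_max)
  # clump on the already FDR-screened set: p_threshold = 1 keeps them all
  out <- suppressWarnings(select_instruments(
    passing, ld = ld, p_threshold = 1, r2_threshold = r2_threshold
  ))
  attr(out, "insufficient") <- nrow(out) < min_snps
  attr(out, "gene") <- target$gene
  out
}
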