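#' Read and validate a pairwise LD matrix
#'
#' The clumping routines take a user-supplied square matrix of pairwise
#' r-squared values (for example exported from an LD reference panel
#' browser). The TSV layout is a header row of snp ids and an id column,
#' i.e. a labelled square matrix.
#'
#' @param path Square TSV with snp ids as first column and header.
#' @return A numeric matrix with snp ids as dimnames, validated by
#'   [validate_ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param ld A square numeric matrix of pairwise r-squared values with snp
#'   ids as dimnames.
#' @export
validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    abort("LD matrix must be square")
  }
  if (is.null(rownames(ld))) abort("LD matrix must carry snp ids as dimnames")
  if (is.null(colnames(ld))) colnames(ld) <- rownames(ld)
  if (!identical(rownames(ld), colnames(ld))) {
    abort("LD matrix row and column snp ids disagree")
  }
  if (max(abs(ld - t(ld))) > 1e-8) abort("LD matrix is not symmetric")
  if (any(ld < 0 | ld > 1 + 1e-12)) abort("LD r-squared values must be in [0, 1]")
  if (max(abs(diag(ld) - 1)) > 1e-8) abort("LD matrix diagonal must be 1")
  ld
}

#' @rdname read_ld_matrix
#' @export
write_ld_matrix <- function(ld, path) {
  out <- tibble::as_tibble(ld)
  out <- dplyr::bind_cols(tibble::tibble(snp = rownames(ld)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

ld_lookup <- function(ld, a, b) {
  # absent pairs are treated as unlinked (r2 = 0); caller warns once
  if (is.null(ld)) return(rep(0, length(b)))
  ok_a <- a %in% rownames(ld)
  ok_b <- b %in% rownames(ld)
  out <- numeric(length(b))
  if (ok_a) out[ok_b] <- ld[a, b[ok_b]]
  out
}

#' Select independent instruments by significance and greedy LD clumping
#'
#' Variants passing the significance threshold are clumped greedily: the
#' most significant remaining variant becomes an index, and every other
#' remaining variant with r-squared at or above `r2_threshold` to it within
#' `window_kb` is removed; the index variants, in selection order, are the
#' instruments. P-value ties are broken by snp id so the result does not
#' depend on input row order. Pairs absent from the LD matrix are treated
#' as unlinked (r-squared 0) with a warning.
#'
#' Defaults mirror genome-wide lipid instrument selection: p <= 5e-8,
#' r-squared < 0.001 within a 10,000 kb window.
#'
#' @param data Summary-statistic tibble with `snp`, `pvalue` and (for
#'   windowed clumping) `chrom`, `pos` columns.
#' @param ld LD r-squared matrix (snp ids as dimnames) or `NULL` for
#'   no-LD-information clumping (significance filter only, with a warning).
#' @param p_threshold Genome-wide significance threshold; default `5e-8`.
#' @param r2_threshold Variants with r-squared `>=` this value to an index
#'   are removed; default 0.001.
#' @param window_kb Clumping window in kilobases around the index variant;
#'   default 10000. Variants beyond the window (or on another chromosome)
#'   are never removed by that index.
#' @return The subset of `data` retained as index variants, in selection
#'   order, with a `clump_order` column.
#' @export
select_instruments <- function(data, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000) {
  if (!"pvalue" %in% names(data)) abort("data must contain a pvalue column")
  passing <- dplyr::filter(data, .data$pvalue <= p_threshold)
  if (nrow(passing) == 0) {
    warn(sprintf("No variant passes p <= %g; returning empty instrument set",
                 p_threshold))
    return(dplyr::mutate(passing, clump_order = integer(0)))
  }
  passing <- dplyr::arrange(passing, .data$pvalue, .data$snp)

  if (is.null(ld)) {
    warn("No LD matrix supplied; variants treated as unlinked")
  } else {
    missing_ld <- setdiff(passing$snp, rownames(ld))
    if (length(missing_ld) > 0) {
      warn(sprintf(
        "%d variant(s) absent from the LD matrix treated as unlinked (r2 = 0)",
        length(missing_ld)
      ))
    }
  }

  have_pos <- all(c("chrom", "pos") %in% names(passing)) &&
    !anyNA(passing$pos)
  remaining <- passing
  kept_idx <- integer(0)
  kept <- list()
  order_i <- 0L
  while (nrow(remaining) > 0) {
    index <- remaining[1, , drop = FALSE]
    order_i <- order_i + 1L
    index$clump_order <- order_i
    kept[[order_i]] <- index
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    r2 <- ld_lookup(ld, index$snp, remaining$snp)
    in_window <- if (have_pos) {
      remaining$chrom == index$chrom &
        abs(remaining$pos - index$pos) <= window_kb * 1000
    } else {
      rep(TRUE, nrow(remaining))
    }
    remaining <- remaining[!(r2 >= r2_threshold & in_window), , drop = FALSE]
  }
  dplyr::bind_rows(kept)
}

#' Select cis instruments around a drug-target gene
#'
#' Restricts a summary-statistic table to the flanked gene window on the
#' gene's chromosome (1-based inclusive GRCh37 coordinates), then clumps at
#' the drug-target LD threshold. Drug-target instrument selection uses a
#' deliberately liberal default (r-squared < 0.3 within +/-100 kb) because
#' cis regions rarely hold many independent signals; targets left with
#' fewer than `min_snps` instruments are flagged insufficient rather than
#' silently analyzed.
#'
#' @inheritParams select_instruments
#' @param target One-row tibble or list with `gene`, `chrom`, `start`,
#'   `end` (see [gene_targets()]).
#' @param flank_bp Flank added to each side of the gene; default 100000.
#' @param r2_threshold Clumping threshold within the cis window; default 0.3.
#' @param min_snps Minimum instruments for the target to count as eligible;
#'   default 2.
#' @return The selected instruments with a `clump_order` column; the
#'   attribute `"insufficient"` is `TRUE` when fewer than `min_snps`
#'   survive.
#' @export
select_cis_instruments <- function(data, target, ld = NULL,
                                   flank_bp = 100000L, p_threshold = 5e-8,
                                   r2_threshold = 0.3, min_snps = 2L,
                                   window_kb = 10000) {
  if (!all(c("chrom", "pos") %in% names(data))) {
    abort("data must contain chrom and pos columns for cis selection")
  }
  window <- dplyr::filter(
    data,
    .data$chrom == as.character(target$chrom),
    .data$pos >= target$start - flank_bp,
    .data$pos <= target$end + flank_bp
  )
  if (nrow(window) == 0) {
    warn(sprintf("No variant falls in the cis window of %s", target$gene))
    out <- dplyr::mutate(window, clump_order = integer(0))
    attr(out, "insufficient") <- TRUE
    attr(out, "gene") <- target$gene
    return(out)
  }
  out <- select_instruments(window, ld = ld, p_threshold = p_threshold,
                            r2_threshold = r2_threshold,
                            window_kb = window_kb)
  attr(out, "insufficient") <- nrow(out) < min_snps
  attr(out, "gene") <- target$gene
  out
}

#' Steiger directionality filter
#'
#' Removes variants that explain more variance in the outcome than in the
#' exposure — the signature of reverse causation. Per variant the variance
#' explained in each trait is computed as `r2 = t^2 / (t^2 + n - 2)` with
#' `t = beta / se`, and the variant is kept iff `r2_exposure > r2_outcome`.
#' With `mode = "ztest"` a variant is only removed when the outcome
#' correlation significantly exceeds the exposure correlation (one-sided
#' z-test on Fisher-transformed correlations at level `alpha`).
#'
#' @param data Harmonized tibble (see [harmonize()]) with per-variant
#'   `n_exposure` and `n_outcome` columns.
#' @param mode `"strict"` (default) keeps a variant iff its exposure
#'   variance explained exceeds its outcome variance explained;
#'   `"ztest"` removes only significantly reverse variants.
#' @param alpha One-sided level for `mode = "ztest"`; default 0.05.
#' @return The filtered tibble with per-variant `r2_exposure`,
#'   `r2_outcome`, `steiger_kept` columns retained for the kept rows; the
#'   removed rows are attached as the `"steiger_removed"` attribute.
#' @export
steiger_filter <- function(data, mode = c("strict", "ztest"), alpha = 0.05) {
  mode <- match.arg(mode)
  assert_harmonized(data, caller = "steiger_filter")
  if (!all(c("n_exposure", "n_outcome") %in% names(data)) ||
      anyNA(data$n_exposure) || anyNA(data$n_outcome)) {
    abort("steiger_filter requires per-variant n_exposure and n_outcome")
  }
  if (any(data$n_exposure <= 2) || any(data$n_outcome <= 2)) {
    abort("Sample sizes must exceed 2 for the Steiger variance-explained formula")
  }
  t_x <- data$beta_exposure / data$se_exposure
  t_y <- data$beta_outcome / data$se_outcome
  r2_x <- t_x^2 / (t_x^2 + data$n_exposure - 2)
  r2_y <- t_y^2 / (t_y^2 + data$n_outcome - 2)
  data$r2_exposure <- r2_x
  data$r2_outcome <- r2_y
  keep <- if (mode == "strict") {
    r2_x > r2_y
  } else {
    z <- (atanh(sqrt(r2_x)) - atanh(sqrt(r2_y))) /
      sqrt(1 / (data$n_exposure - 3) + 1 / (data$n_outcome - 3))
    # remove only when the outcome correlation is significantly larger
    !(pnorm(z) < alpha)
  }
  data$steiger_kept <- keep
  out <- data[keep, , drop = FALSE]
  attr(out, "steiger_removed") <- data[!keep, , drop = FALSE]
  attr(out, "harmonization") <- attr(data, "harmonization")
  out
}

#' Instrument-strength F statistic
#'
#' `F = R2 (n - 1 - k) / ((1 - R2) k)` where `R2` is the proportion of
#' exposure variance explained by the `k` instruments in a sample of size
#' `n`. Instruments with `F < 10` are conventionally flagged as weak.
#'
#' @param R2 Proportion of variance explained, in `[0, 1)`.
#' @param n Exposure GWAS sample size; must exceed `k + 1`.
#' @param k Number of instruments, `>= 1`.
#' @return The F statistic (scalar).
#' @seealso [is_weak_instrument()], [instrument_strength()]
#' @export
#' @examples
#' f_statistic(0.5, 12, 1) # exactly 10, the weak-instrument boundary
f_statistic <- function(R2, n, k) {
  if (any(R2 < 0) || any(R2 >= 1)) abort("R2 must lie in [0, 1)")
  if (any(k < 1)) abort("k must be >= 1")
  if (any(n <= k + 1)) abort("n must exceed k + 1")
  R2 * (n - 1 - k) / ((1 - R2) * k)
}

#' @rdname f_statistic
#' @param f An F statistic.
#' @param threshold Weak-instrument cutoff; default 10.
#' @export
is_weak_instrument <- function(f, threshold = 10) f < threshold

#' Per-variant variance explained and instrument diagnostics
#'
#' Summarizes the strength of an instrument set: per-variant variance
#' explained, their sum `R2` (an independence approximation), and the
#' F statistic. Two variance-explained conventions are available:
#' `"tstat"` (default) uses `t^2 / (t^2 + n - 2)`; `"eaf"` uses
#' `2 eaf (1 - eaf) beta^2`, valid for a standardized (unit-variance)
#' trait.
#'
#' @param data Harmonized tibble or any tibble with `beta_exposure`,
#'   `se_exposure`, `n_exposure` (and `eaf_exposure` for
#'   `method = "eaf"`).
#' @param method Variance-explained convention.
#' @return A one-row tibble with `R2`, `k`, `n`, `F`, `weak`, and the
#'   per-variant values as the list-column `per_snp_r2`.
#' @export
instrument_strength <- function(data, method = c("tstat", "eaf")) {
  method <- match.arg(method)
  assert_harmonized(data, caller = "instrument_strength")
  n <- unique(data$n_exposure)
  if (length(n) != 1 || !is.finite(n)) n <- max(data$n_exposure, na.rm = TRUE)
  per <- if (method == "tstat") {
    t2 <- (data$beta_exposure / data$se_exposure)^2
    t2 / (t2 + data$n_exposure - 2)
  } else {
    if (!"eaf_exposure" %in% names(data) || anyNA(data$eaf_exposure)) {
      abort("method = 'eaf' requires complete eaf_exposure values")
    }
    2 * data$eaf_exposure * (1 - data$eaf_exposure) * data$beta_exposure^2
  }
  R2 <- sum(per)
  k <- nrow(data)
  f <- f_statistic(R2, n, k)
  tibble::tibble(
    R2 = R2, k = k, n = n, F = f,
    weak = is_weak_instrument(f),
    per_snp_r2 = list(per)
  )
}
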