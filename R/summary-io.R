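#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited per-variant association table into the
#' standard column vocabulary used throughout the package: `snp`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#' `n`. Column mapping is explicit configuration rather than sniffed from
#' headers, so a run is reproducible across GWAS dialects.
#'
#' Rows with a non-numeric or missing `beta`/`se`, or `se <= 0`, are dropped
#' and counted; alleles are upper-cased. The parse report (rows read / kept /
#' dropped, with per-reason counts) is attached as the `"parse_report"`
#' attribute and retrievable with [parse_report()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard field names to
#'   source column names, e.g. `c(snp = "rsid", beta = "b", se = "se")`.
#'   Standard names absent from the map are looked up verbatim. Mandatory
#'   fields: `snp`, `effect_allele`, `other_allele`, `beta`, `se`.
#' @param delim Field delimiter; `NULL` (default) tries tab then comma.
#'
#' @return A tibble of variant associations (one row per kept input row)
#'   with a `"parse_report"` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("rsid\tea\toa\tb\ts", "rs1\ta\tg\t0.1\t0.01"), tf)
#' x <- read_summary_table(tf, c(
#'   snp = "rsid", effect_allele = "ea",
#'   other_allele = "oa", beta = "b", se = "s"
#' ))
#' parse_report(x)$rows_kept
read_summary_table <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (file.size(path) == 0) abort(paste0("Empty input file: ", path))

  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) abort(paste0("Empty input file: ", path))

  map <- setNames(SUMMARY_COLS, SUMMARY_COLS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMMARY_COLS)
    if (length(bad) > 0) {
      abort(paste0("Unknown standard field(s) in column_map: ",
                   paste(bad, collapse = ", ")))
    }
    map[names(column_map)] <- column_map
  }
  missing_mandatory <- MANDATORY_COLS[!map[MANDATORY_COLS] %in% names(raw)]
  if (length(missing_mandatory) > 0) {
    abort(paste0(
      "Mandatory column(s) not found in ", path, ": ",
      paste(sprintf("%s (mapped to '%s')", missing_mandatory,
                    map[missing_mandatory]), collapse = ", ")
    ))
  }
  present <- SUMMARY_COLS[map %in% names(raw)]
  out <- tibble::as_tibble(setNames(
    lapply(present, function(f) raw[[map[[f]]]]), present
  ))

  numeric_cols <- intersect(c("pos", "eaf", "beta", "se", "pvalue", "n"),
                            names(out))
  for (col in numeric_cols) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)

  rows_read <- nrow(out)
  drop_reasons <- c(
    nonnumeric_beta_se = 0L, nonpositive_se = 0L, invalid_alleles = 0L
  )

  bad_num <- !is.finite(out$beta) | !is.finite(out$se)
  drop_reasons[["nonnumeric_beta_se"]] <- sum(bad_num)
  out <- out[!bad_num, , drop = FALSE]

  bad_se <- out$se <= 0
  drop_reasons[["nonpositive_se"]] <- sum(bad_se)
  out <- out[!bad_se, , drop = FALSE]

  valid_allele <- out$effect_allele %in% names(DNA_COMPLEMENT) &
    out$other_allele %in% names(DNA_COMPLEMENT) &
    out$effect_allele != out$other_allele
  drop_reasons[["invalid_alleles"]] <- sum(!valid_allele)
  out <- out[valid_allele, , drop = FALSE]

  if ("pos" %in% names(out)) out$pos <- as.integer(out$pos)
  if ("n" %in% names(out)) out$n <- as.integer(out$n)

  attr(out, "parse_report") <- list(
    path = path,
    rows_read = rows_read,
    rows_kept = nrow(out),
    rows_dropped = rows_read - nrow(out),
    dropped = as.list(drop_reasons)
  )
  out
}

#' Retrieve the parse report attached by [read_summary_table()]
#'
#' @param x A tibble returned by [read_summary_table()].
#' @return A list with `rows_read`, `rows_kept`, `rows_dropped` and a
#'   `dropped` list of per-reason counts.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Gene windows of the lipid-lowering drug targets
#'
#' Loads the packaged table of drug-target genes with their GRCh37
#' coordinates, the lipid each target proxies (LDL-C or TG), and whether
#' enough cis instruments were available to treat the target as eligible.
#'
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`,
#'   `proxy_trait`, `eligible`.
#' @export
#' @examples
#' gene_targets()
gene_targets <- function() {
  path <- system.file("extdata", "gene_targets.tsv", package = "targetmr")
  readr::read_tsv(path, col_types = readr::cols(
    gene = "c", chrom = "c", start = "i", end = "i",
    proxy_trait = "c", eligible = "l"
  ), progress = FALSE)
}

complement_alleles <- function(a) unname(DNA_COMPLEMENT[a])

is_palindromic <- function(ea, oa) complement_alleles(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each shared variant's outcome association to the exposure's
#' effect-allele coding. Matching is attempted as-is, with swapped alleles
#' (effect/other exchanged: outcome beta negated, eaf reflected), and on the
#' complementary strand. Palindromic variants (A/T or G/C), whose strand
#' cannot be resolved from alleles, are oriented by comparing effect-allele
#' frequencies: frequencies on the same side of 0.5 keep the coding,
#' opposite sides flip it, and a frequency inside the ambiguity window
#' around 0.5 (or a missing frequency) drops the variant. Variants whose
#' alleles cannot be reconciled under any of these actions are strictly
#' excluded.
#'
#' @param exposure,outcome Tibbles in the standard summary-statistic
#'   vocabulary (see [read_summary_table()]); each must have unique `snp`.
#' @param palindrome_eaf_window Half-open ambiguity bound: a palindromic
#'   variant with either trait's eaf in
#'   `[palindrome_eaf_window, 1 - palindrome_eaf_window]` is dropped.
#'   Default 0.42, i.e. frequencies in \[0.42, 0.58\] are uninformative.
#'
#' @return A tibble with one row per aligned variant: `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `pvalue_exposure`, `n_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `pvalue_outcome`, `n_outcome`, and an
#'   `action` provenance column. Per-reason drop counts live in the
#'   `"harmonization"` attribute (see [harmonization_report()]); kept plus
#'   dropped always equals the size of the snp intersection.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.42) {
  stopifnot(palindrome_eaf_window > 0, palindrome_eaf_window < 0.5)
  for (nm in c("exposure", "outcome")) {
    tbl <- if (nm == "exposure") exposure else outcome
    if (anyDuplicated(tbl$snp) > 0) {
      abort(paste0(
        "Duplicate snp ids in ", nm,
        " table; deduplicate deliberately before harmonizing"
      ))
    }
  }

  keep_or_na <- function(tbl, col) {
    if (col %in% names(tbl)) tbl[[col]] else rep(NA_real_, nrow(tbl))
  }
  exp_tbl <- tibble::tibble(
    snp = exposure$snp,
    chrom = if ("chrom" %in% names(exposure)) exposure$chrom else NA_character_,
    pos = if ("pos" %in% names(exposure)) exposure$pos else NA_integer_,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_exposure = exposure$beta,
    se_exposure = exposure$se,
    eaf_exposure = keep_or_na(exposure, "eaf"),
    pvalue_exposure = keep_or_na(exposure, "pvalue"),
    n_exposure = keep_or_na(exposure, "n")
  )
  out_tbl <- tibble::tibble(
    snp = outcome$snp,
    ea_out = outcome$effect_allele,
    oa_out = outcome$other_allele,
    beta_outcome = outcome$beta,
    se_outcome = outcome$se,
    eaf_outcome = keep_or_na(outcome, "eaf"),
    pvalue_outcome = keep_or_na(outcome, "pvalue"),
    n_outcome = keep_or_na(outcome, "n")
  )
  joined <- dplyr::inner_join(exp_tbl, out_tbl, by = "snp")
  if (nrow(joined) == 0) abort("No shared snp ids between exposure and outcome")

  lo <- palindrome_eaf_window
  hi <- 1 - palindrome_eaf_window

  resolve_row <- function(ea, oa, ea_o, oa_o, eaf_x, eaf_y) {
    # returns action + whether to negate outcome beta / reflect outcome eaf
    if (is_palindromic(ea, oa)) {
      if (!(ea_o %in% c(ea, oa)) || !(oa_o %in% c(ea, oa)) || ea_o == oa_o) {
        return(list(action = "dropped", reason = "inconsistent_alleles"))
      }
      if (!is.finite(eaf_x) || !is.finite(eaf_y) ||
          (eaf_x >= lo && eaf_x <= hi) || (eaf_y >= lo && eaf_y <= hi)) {
        return(list(action = "dropped", reason = "palindromic_ambiguous"))
      }
      same_side <- (eaf_x < 0.5) == (eaf_y < 0.5)
      if (same_side) {
        list(action = "palindromic_kept", flip = FALSE)
      } else {
        list(action = "palindromic_flipped", flip = TRUE)
      }
    } else if (ea_o == ea && oa_o == oa) {
      list(action = "kept", flip = FALSE)
    } else if (ea_o == oa && oa_o == ea) {
      list(action = "flipped", flip = TRUE)
    } else if (complement_alleles(ea_o) == ea && complement_alleles(oa_o) == oa) {
      list(action = "complemented", flip = FALSE)
    } else if (complement_alleles(ea_o) == oa && complement_alleles(oa_o) == ea) {
      list(action = "complemented_flipped", flip = TRUE)
    } else {
      list(action = "dropped", reason = "inconsistent_alleles")
    }
  }

  res <- purrr::pmap(
    list(joined$effect_allele, joined$other_allele, joined$ea_out,
         joined$oa_out, joined$eaf_exposure, joined$eaf_outcome),
    resolve_row
  )
  joined$action <- purrr::map_chr(res, "action")
  reason <- purrr::map_chr(res, function(r) r$reason %||% NA_character_)
  flip <- purrr::map_lgl(res, function(r) isTRUE(r$flip))

  joined$beta_outcome[flip] <- -joined$beta_outcome[flip]
  joined$eaf_outcome[flip] <- 1 - joined$eaf_outcome[flip]

  dropped <- joined$action == "dropped"
  drop_counts <- table(factor(
    reason[dropped],
    levels = c("inconsistent_alleles", "palindromic_ambiguous")
  ))
  kept <- joined[!dropped, , drop = FALSE]
  kept$ea_out <- NULL
  kept$oa_out <- NULL

  attr(kept, "harmonization") <- list(
    n_intersection = nrow(joined),
    n_kept = nrow(kept),
    dropped = as.list(drop_counts),
    dropped_snps = joined$snp[dropped],
    palindrome_eaf_window = palindrome_eaf_window
  )
  kept
}

#' Retrieve the harmonization report attached by [harmonize()]
#'
#' @param x A tibble returned by [harmonize()].
#' @return A list with the intersection size, kept count, per-reason drop
#'   counts and the dropped snp ids.
#' @export
harmonization_report <- function(x) attr(x, "harmonization")

#' Write a harmonized instrument set as TSV
#'
#' Writes the aligned exposure/outcome table with its per-variant
#' orientation provenance (`action` column), and the harmonization report
#' as a JSON side-car when `report_path` is given.
#'
#' @param x Tibble from [harmonize()].
#' @param path Output TSV path.
#' @param report_path Optional path for the JSON parse/drop report.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path, report_path = NULL) {
  readr::write_tsv(x, path, progress = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(harmonization_report(x), report_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
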