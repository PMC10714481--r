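# shared fixture builders (all fixtures are generated in code)

make_harmonized <- function(bx, sx, by, sy,
                            n_exposure = 100000L, n_outcome = 100000L,
                            snp = sprintf("rs%03d", seq_along(bx))) {
  tibble::tibble(
    snp = snp,
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    n_exposure = n_exposure, n_outcome = n_outcome
  )
}

make_assoc <- function(snp, ea, oa, beta, se, eaf = NA_real_,
                       chrom = "19", pos = seq_along(snp) * 1000L,
                       pvalue = 2 * pnorm(-abs(beta / se)),
                       n = 100000L) {
  tibble::tibble(
    snp = snp, chrom = chrom, pos = as.integer(pos),
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = as.integer(n)
  )
}

write_tmp_table <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

named_ld <- function(ids, m) {
  dimnames(m) <- list(ids, ids)
  m
}
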