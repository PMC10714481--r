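test_that("well-formed tables parse row for row with upper-cased alleles", {
  tf <- write_tmp_table(c(
    "snp\tchrom\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tn",
    "rs1\t19\t100\ta\tg\t0.2\t0.10\t0.01\t1e-10\t1000",
    "rs2\t19\t200\tC\tT\t0.5\t-0.05\t0.02\t0.01\t1000",
    "rs3\t19\t300\tG\tA\t0.9\t0.00\t0.03\t0.9\t1000"
  ))
  x <- read_summary_table(tf)
  expect_equal(nrow(x), 3)
  expect_equal(parse_report(x)$rows_dropped, 0)
  expect_equal(x$effect_allele, c("A", "C", "G"))
  expect_equal(x$other_allele, c("G", "T", "A"))
  expect_equal(x$beta, c(0.10, -0.05, 0))
})

test_that("rows violating invariants are dropped and counted by reason", {
  tf <- write_tmp_table(c(
    "snp\teffect_allele\tother_allele\tbeta\tse",
    "rs1\tA\tG\t0.1\t0.01",
    "rs2\tA\tG\t0.1\t0",       # nonpositive se
    "rs3\tA\tG\tx\t0.01",      # non-numeric beta
    "rs4\tA\tA\t0.1\t0.01"     # identical alleles
  ))
  x <- read_summary_table(tf)
  expect_equal(nrow(x), 1)
  rep <- parse_report(x)
  expect_equal(rep$dropped$nonpositive_se, 1)
  expect_equal(rep$dropped$nonnumeric_beta_se, 1)
  expect_equal(rep$dropped$invalid_alleles, 1)
  expect_equal(rep$rows_read, rep$rows_kept + rep$rows_dropped)
})

test_that("column mapping is explicit and missing mandatory columns are named", {
  tf <- write_tmp_table(c("rsid\tea\toa\tb\ts", "rs1\tA\tG\t0.1\t0.01"))
  x <- read_summary_table(tf, c(
    snp = "rsid", effect_allele = "ea", other_allele = "oa",
    beta = "b", se = "s"
  ))
  expect_equal(x$snp, "rs1")
  expect_error(read_summary_table(tf, c(snp = "rsid")), "effect_allele")
  expect_error(read_summary_table(tempfile()), "not found")
  tf_empty <- write_tmp_table(character(0))
  expect_error(read_summary_table(tf_empty), "[Ee]mpty")
})

test_that("gene target windows reproduce the published panel", {
  gt <- gene_targets()
  expect_equal(nrow(gt), 11)
  ldlr <- gt[gt$gene == "LDLR", ]
  expect_equal(ldlr$chrom, "19")
  expect_equal(ldlr$start, 11200038L)
  expect_equal(ldlr$end, 11244492L)
  expect_true(ldlr$eligible)
  expect_false(any(gt$eligible[gt$gene %in% c("PPARA", "ACLY")]))
  expect_equal(sum(gt$eligible), 9)
  expect_true(all(gt$start < gt$end))
  expect_true(all(gt$proxy_trait %in% c("LDL-C", "TG")))
})

test_that("swapped outcome alleles are negated and eaf reflected", {
  exposure <- make_assoc("rs1", "A", "G", 0.10, 0.01, eaf = 0.3)
  outcome <- make_assoc("rs1", "G", "A", -0.05, 0.01, eaf = 0.7)
  h <- harmonize(exposure, outcome)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.3)
  expect_equal(h$action, "flipped")
})

test_that("irreconcilable alleles are strictly excluded", {
  exposure <- make_assoc("rs1", "A", "G", 0.10, 0.01)
  outcome <- make_assoc("rs1", "A", "C", 0.05, 0.01)
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h), 0)
  expect_equal(harmonization_report(h)$dropped$inconsistent_alleles, 1)
})

test_that("strand complements resolve before comparison", {
  exposure <- make_assoc("rs1", "A", "G", 0.10, 0.01)
  outcome <- make_assoc("rs1", "T", "C", 0.05, 0.01) # complement of A/G
  h <- harmonize(exposure, outcome)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$action, "complemented")
  outcome2 <- make_assoc("rs1", "C", "T", 0.05, 0.01) # swapped complement
  h2 <- harmonize(exposure, outcome2)
  expect_equal(h2$beta_outcome, -0.05)
})

test_that("palindromic orientation follows the frequency-inference oracle", {
  # oracle: enumerate the four orientation cases for an A/T variant.
  # Outcome effect alleles whose frequencies land on the opposite side of
  # 0.5 from the exposure's must be the complement-swap -> negate.
  cases <- tibble::tribble(
    ~eaf_x, ~eaf_y, ~expect_beta, ~expect_action,
    0.10, 0.12, 0.05, "palindromic_kept",
    0.10, 0.88, -0.05, "palindromic_flipped",
    0.90, 0.88, 0.05, "palindromic_kept",
    0.90, 0.12, -0.05, "palindromic_flipped"
  )
  for (i in seq_len(nrow(cases))) {
    exposure <- make_assoc("rs1", "A", "T", 0.10, 0.01,
                           eaf = cases$eaf_x[i])
    outcome <- make_assoc("rs1", "A", "T", 0.05, 0.01,
                          eaf = cases$eaf_y[i])
    h <- harmonize(exposure, outcome)
    expect_equal(h$beta_outcome, cases$expect_beta[i])
    expect_equal(h$action, cases$expect_action[i])
  }
})

test_that("palindromic variants with uninformative frequencies are dropped", {
  exposure <- make_assoc("rs1", "G", "C", 0.10, 0.01, eaf = 0.30)
  outcome <- make_assoc("rs1", "G", "C", 0.05, 0.01, eaf = 0.48)
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h), 0)
  expect_equal(harmonization_report(h)$dropped$palindromic_ambiguous, 1)
  # missing frequency is equally uninformative
  outcome_na <- make_assoc("rs1", "G", "C", 0.05, 0.01, eaf = NA_real_)
  expect_equal(nrow(harmonize(exposure, outcome_na)), 0)
})

test_that("duplicate snp ids are rejected rather than silently merged", {
  exposure <- make_assoc(c("rs1", "rs1"), "A", "G", 0.1, 0.01)
  outcome <- make_assoc("rs1", "A", "G", 0.1, 0.01)
  expect_error(harmonize(exposure, outcome), "[Dd]uplicate")
})

test_that("harmonization is idempotent", {
  sim <- simulate_two_sample(n_snps = 40, n_instruments = 20, seed = 11)
  h <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome table from the harmonized set and harmonize again
  outcome2 <- tibble::tibble(
    snp = h$snp, chrom = h$chrom, pos = h$pos,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h$eaf_outcome, beta = h$beta_outcome, se = h$se_outcome,
    pvalue = h$pvalue_outcome, n = h$n_outcome
  )
  h2 <- harmonize(sim$exposure, outcome2)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_equal(h2$eaf_outcome, h$eaf_outcome)
  expect_equal(nrow(h2), nrow(h))
})

test_that("flipping the whole outcome file leaves the harmonized set identical", {
  sim <- simulate_two_sample(n_snps = 40, n_instruments = 20, seed = 12)
  h <- harmonize(sim$exposure, sim$outcome)
  flipped <- dplyr::mutate(
    sim$outcome,
    tmp = .data$effect_allele,
    effect_allele = .data$other_allele,
    other_allele = .data$tmp,
    beta = -.data$beta,
    eaf = 1 - .data$eaf
  )
  flipped$tmp <- NULL
  h2 <- harmonize(sim$exposure, flipped)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_equal(h2$eaf_outcome, h$eaf_outcome)
  expect_equal(h2$se_outcome, h$se_outcome)
})

test_that("kept plus dropped equals the snp intersection", {
  exposure <- make_assoc(
    c("rs1", "rs2", "rs3", "rs4"),
    c("A", "A", "A", "G"), c("G", "T", "G", "C"),
    0.1, 0.01, eaf = c(0.3, 0.1, 0.3, 0.49)
  )
  outcome <- make_assoc(
    c("rs1", "rs2", "rs3", "rs4"),
    c("A", "T", "A", "G"), c("G", "A", "C", "C"),
    0.1, 0.01, eaf = c(0.3, 0.9, 0.3, 0.49)
  )
  h <- harmonize(exposure, outcome)
  rep <- harmonization_report(h)
  expect_equal(rep$n_kept + sum(unlist(rep$dropped)), rep$n_intersection)
  expect_equal(rep$n_intersection, 4)
})
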