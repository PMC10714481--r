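test_that("greedy clumping keeps the most significant of a linked pair", {
  ids <- c("rs_a", "rs_b")
  d <- make_assoc(ids, "A", "G", c(0.1, 0.1), 0.01,
                  pos = c(100000L, 105000L),
                  pvalue = c(1e-10, 1e-8))
  ld <- named_ld(ids, matrix(c(1, 0.5, 0.5, 1), 2))
  out <- select_instruments(d, ld, r2_threshold = 0.3, window_kb = 10)
  expect_equal(out$snp, "rs_a")
  # unlinked pair: both kept regardless of p order
  ld0 <- named_ld(ids, diag(2))
  out0 <- select_instruments(d, ld0, r2_threshold = 0.3, window_kb = 10)
  expect_setequal(out0$snp, ids)
})

test_that("clumping a linked chain matches the brute-force greedy oracle", {
  # r2(1,2) = r2(2,3) = 0.5, r2(1,3) = 0.05; p ascends with position.
  # Oracle (enumerated by hand): index rs1 removes rs2; rs3 survives.
  ids <- c("rs1", "rs2", "rs3")
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.05
  d <- make_assoc(ids, "A", "G", 0.1, 0.01,
                  pos = c(1e5, 1.1e5, 1.2e5),
                  pvalue = c(1e-12, 1e-10, 1e-9))
  out <- select_instruments(d, named_ld(ids, m),
                            r2_threshold = 0.3, window_kb = 100)
  expect_equal(out$snp, c("rs1", "rs3"))
})

test_that("clumping is invariant to input row order with snp-id tie-breaks", {
  set.seed(7)
  n <- 20
  ids <- sprintf("rs%02d", 1:n)
  r <- matrix(runif(n * n, 0, 0.8), n)
  r2 <- (r + t(r)) / 2
  diag(r2) <- 1
  pv <- rep(1e-10, n) # all tied: order must come from snp ids alone
  d <- make_assoc(ids, "A", "G", 0.1, 0.01, pos = (1:n) * 1000L,
                  pvalue = pv)
  ld <- named_ld(ids, r2)
  out1 <- select_instruments(d, ld, r2_threshold = 0.3, window_kb = 1000)
  shuffled <- d[sample(n), ]
  out2 <- select_instruments(shuffled, ld, r2_threshold = 0.3,
                             window_kb = 1000)
  expect_equal(out1$snp, out2$snp)
  # every removed variant is linked to some retained index within window
  removed <- setdiff(ids, out1$snp)
  for (s in removed) {
    expect_true(any(ld[s, out1$snp] >= 0.3))
  }
})

test_that("no passing variant yields an empty set with a warning, not an error", {
  d <- make_assoc("rs1", "A", "G", 0.01, 0.01, pvalue = 0.5)
  expect_warning(out <- select_instruments(d, NULL), "No variant")
  expect_equal(nrow(out), 0)
})

test_that("variants missing from the LD matrix are treated as unlinked with warning", {
  ids <- c("rs1", "rs2")
  d <- make_assoc(ids, "A", "G", 0.1, 0.01, pos = c(1e5, 1.01e5),
                  pvalue = c(1e-10, 1e-9))
  ld <- named_ld("rs1", matrix(1, 1, 1))
  expect_warning(out <- select_instruments(d, ld, r2_threshold = 0.3,
                                           window_kb = 100),
                 "absent from the LD matrix")
  expect_setequal(out$snp, ids)
})

test_that("cis windows around gene targets use inclusive flanked bounds", {
  ldlr <- gene_targets()[gene_targets()$gene == "LDLR", ]
  # LDLR spans 19:11,200,038-11,244,492; with a 100 kb flank the lower
  # bound is 11,100,038: one base below is out, the gene start is in.
  d <- make_assoc(c("rs_out", "rs_edge", "rs_in"), "A", "G", 0.1, 0.01,
                  chrom = "19",
                  pos = c(11100037L, 11100038L, 11200038L),
                  pvalue = 1e-10)
  out <- suppressWarnings(select_cis_instruments(d, ldlr, min_snps = 1))
  expect_setequal(out$snp, c("rs_edge", "rs_in"))
  # wrong chromosome excludes everything
  d_chr <- dplyr::mutate(d, chrom = "1")
  out_chr <- suppressWarnings(select_cis_instruments(d_chr, ldlr))
  expect_equal(nrow(out_chr), 0)
})

test_that("targets left with too few instruments are flagged insufficient", {
  ldlr <- gene_targets()[gene_targets()$gene == "LDLR", ]
  d <- make_assoc("rs1", "A", "G", 0.1, 0.01, chrom = "19",
                  pos = 11210000L, pvalue = 1e-10)
  out <- suppressWarnings(select_cis_instruments(d, ldlr, min_snps = 2))
  expect_equal(nrow(out), 1)
  expect_true(attr(out, "insufficient"))
})

test_that("Steiger filtering matches the per-variant variance-explained oracle", {
  # hand arithmetic: r2 = t^2 / (t^2 + n - 2)
  h <- make_harmonized(
    bx = c(10, 2, 5) * 0.01, sx = 0.01,
    by = c(2, 10, 6) * 0.01, sy = 0.01,
    n_exposure = c(1000L, 1000L, 100002L),
    n_outcome = c(1000L, 1000L, 10002L)
  )
  out <- steiger_filter(h)
  # rs001: t 10 vs 2 equal n -> kept; rs002: reverse -> removed
  # rs003: r2_exp = 25/100025 < r2_out = 36/10036 -> removed
  expect_equal(out$snp, "rs001")
  removed <- attr(out, "steiger_removed")
  expect_setequal(removed$snp, c("rs002", "rs003"))
  expect_equal(removed$r2_exposure[removed$snp == "rs003"], 25 / 100025)
  expect_equal(removed$r2_outcome[removed$snp == "rs003"], 36 / 10036)
})

test_that("Steiger filter equals a brute-force oracle on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    h <- make_harmonized(
      bx = rnorm(k, 0, 0.05), sx = runif(k, 0.005, 0.02),
      by = rnorm(k, 0, 0.05), sy = runif(k, 0.005, 0.02),
      n_exposure = sample(1e4:1e5, 1), n_outcome = sample(1e4:1e5, 1)
    )
    out <- steiger_filter(h)
    oracle_keep <- vapply(seq_len(k), function(j) {
      tx <- h$beta_exposure[j] / h$se_exposure[j]
      ty <- h$beta_outcome[j] / h$se_outcome[j]
      tx^2 / (tx^2 + h$n_exposure[j] - 2) >
        ty^2 / (ty^2 + h$n_outcome[j] - 2)
    }, logical(1))
    expect_equal(out$snp, h$snp[oracle_keep])
  }
})

test_that("Steiger filter rejects unusable sample sizes", {
  h <- make_harmonized(0.1, 0.01, 0.1, 0.01, n_exposure = 2L)
  expect_error(steiger_filter(h), "exceed 2")
  h2 <- make_harmonized(0.1, 0.01, 0.1, 0.01)
  h2$n_exposure <- NULL
  expect_error(steiger_filter(h2), "n_exposure")
})

test_that("F statistic reproduces hand arithmetic and boundary flags", {
  expect_equal(f_statistic(0.5, 12, 1), 10) # the weak-instrument boundary
  expect_equal(f_statistic(0, 100, 5), 0)
  expect_false(is_weak_instrument(10))
  expect_true(is_weak_instrument(9.999))
  expect_error(f_statistic(1, 100, 1), "R2")
  expect_error(f_statistic(0.5, 3, 2), "n must exceed")
})

test_that("F statistic is monotone in R2 and n, antitone in k", {
  r2 <- seq(0.01, 0.9, length.out = 20)
  expect_true(all(diff(f_statistic(r2, 1000, 10)) > 0))
  ns <- seq(100, 10000, by = 100)
  expect_true(all(diff(f_statistic(0.1, ns, 10)) > 0))
  ks <- 1:50
  expect_true(all(diff(f_statistic(0.1, 1000, ks)) < 0))
})

test_that("instrument strength sums per-variant variance explained", {
  h <- make_harmonized(bx = c(0.05, 0.04), sx = 0.005,
                       by = c(0.01, 0.01), sy = 0.005,
                       n_exposure = 50000L)
  out <- instrument_strength(h)
  t2 <- (h$beta_exposure / h$se_exposure)^2
  expect_equal(out$R2, sum(t2 / (t2 + 50000 - 2)))
  expect_equal(out$F, f_statistic(out$R2, 50000, 2))
  # eaf convention
  h$eaf_exposure <- c(0.3, 0.4)
  out_eaf <- instrument_strength(h, method = "eaf")
  expect_equal(out_eaf$R2,
               sum(2 * h$eaf_exposure * (1 - h$eaf_exposure) *
                     h$beta_exposure^2))
})

test_that("LD matrices round-trip through TSV and are validated", {
  ids <- c("rs1", "rs2", "rs3")
  m <- named_ld(ids, matrix(c(1, .2, 0, .2, 1, .5, 0, .5, 1), 3))
  tf <- tempfile(fileext = ".tsv")
  write_ld_matrix(m, tf)
  m2 <- read_ld_matrix(tf)
  expect_equal(m2, m)
  bad <- m
  bad[1, 2] <- 0.9 # breaks symmetry
  expect_error(validate_ld_matrix(bad), "symmetric")
  bad2 <- m
  diag(bad2) <- 0.5
  expect_error(validate_ld_matrix(bad2), "diagonal")
})
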