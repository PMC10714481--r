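# targetmr

Drug-target Mendelian randomization (MR) from GWAS summary statistics, in R.

## What this package is for

Two-sample MR treats genetic variants as instrumental variables: a variant's
effect on an exposure (`b_X`) and on an outcome (`b_Y`), estimated in two
different GWAS samples, imply a causal effect `θ = b_Y / b_X` if the variant
satisfies the relevance, independence and exclusion-restriction assumptions.
*Drug-target* MR restricts the instruments to variants in or near the gene
encoding a drug's protein target (for lipid-lowering therapy: *LDLR*,
*HMGCR*, *PCSK9*, *NPC1L1*, *APOB*, *CETP*, *LPL*, *APOC3*, *ANGPTL3*), so
the instruments proxy pharmacological modulation of that target.

`targetmr` implements the full analysis pipeline for people who work with
summary statistics rather than individual-level data:

- **IO and harmonization** — explicit column mapping for summary tables,
  allele alignment (swaps, strand complements, frequency-resolved
  palindromes), with per-variant provenance and per-reason drop counts.
- **Instrument selection** — greedy LD clumping against a user-supplied
  r² matrix (genome-wide defaults `p ≤ 5e-8`, `r² < 0.001`/10,000 kb;
  cis-target defaults `r² < 0.3` within ±100 kb; eQTL instruments within
  ±1 Mb at MAF > 0.01 and BH-FDR < 0.05), Steiger directionality
  filtering, and the instrument-strength statistic
  `F = R²(n−1−k) / ((1−R²)k)` with the conventional `F < 10` weak-instrument
  flag.
- **Estimators** — ratio, inverse-variance weighted (fixed and
  multiplicative random effects), MR-Egger with its intercept test,
  weighted median, weighted mode, profile maximum likelihood, and
  multivariable MR.
- **Diagnostics** — Cochran Q, leave-one-out, approximate statistical
  power, Benjamini–Hochberg FDR, and fixed/DerSimonian–Laird meta-analysis
  across consortia with an automatic heterogeneity-based switch.
- **Two-step mediation** — decomposition of a total effect into
  indirect (`βA·βB`) and direct (`βC − βA·βB`) parts with delta-method
  uncertainty and proportion mediated.
- **Colocalization** — Wakefield approximate Bayes factors accumulated in
  log space into the five posterior probabilities PP.H0–PP.H4, with the
  `PP.H4 > 0.85` strong-colocalization rule.
- **Synthetic data** — generators for two-sample summary statistics (LD
  blocks, pleiotropy, reverse causation), mediation chains, and
  colocalization regions under each hypothesis, so the whole pipeline is
  exercisable and testable without any downloads.

Everything is tibble-in / tibble-out and pipe-friendly; scan results have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a cis region where lowering the lipid (the drug effect) extends
lifespan with true effect 0.15 per unit, then run the full scan:

```r
library(targetmr)

sim <- simulate_two_sample(
  n_snps = 60, n_instruments = 20, theta = -0.15,  # -0.15 per unit *raising*
  n_exposure = 300000, n_outcome = 500000,
  ld_block_size = 5, ld_rho = 0.6, seed = 2024
)
target <- tibble::tibble(
  gene = "LDLR", chrom = "19",
  start = 11200038L, end = 11244492L,
  proxy_trait = "LDL-C", eligible = TRUE
)
scan <- run_drug_target_mr(
  sim$exposure, sim$outcome, target, ld = sim$ld,
  n_boot = 500, seed = 1
)
scan
#> <mr_target_scan>
#>   targets analyzed: 1 (of 1 attempted)
#>   outcome type: quantitative; effect direction: per unit lipid lowering
#>   main (IVW) estimates:
#> # A tibble: 1 × 7
#>   gene  estimate ci_lower ci_upper  p_value  q_value n_snp
#>   <chr>    <dbl>    <dbl>    <dbl>    <dbl>    <dbl> <int>
#> 1 LDLR     0.149    0.128    0.169 3.41e-45 3.41e-45     4
```

The 20 causal variants sit in LD blocks of five; clumping at `r² < 0.3`
keeps one index variant per block, hence 4 instruments. The IVW estimate
0.149 (95% CI 0.128–0.169) recovers the generating effect of +0.15 per
unit lipid lowering — reported under the lowering sign convention, so a
positive estimate reads "lowering the lipid extends lifespan".

```r
glance(scan)[, c("gene", "estimate", "q_value", "F", "q_p_value")]
#> # A tibble: 1 × 5
#>   gene  estimate  q_value     F q_p_value
#> 1 LDLR     0.149 3.41e-45 1366.     0.851
```

`F = 1366` rules out weak-instrument bias; the Cochran Q p-value 0.85
shows no heterogeneity. Mediation decomposition from reported effects —
a total lifespan effect of 0.164 that drops to a direct 0.127 after
adjusting for coronary disease:

```r
mediation_from_total_direct(total = 0.164, direct = 0.127)
#> # A tibble: 1 × 4
#>   total direct indirect proportion_mediated_pct
#> 1 0.164  0.127    0.037                    22.6
```

i.e. an indirect effect of 0.037, with ~22.6% of the total effect carried
through the mediator.

## Documentation

The methods vignette (`vignettes/drug-target-mr.Rmd`) documents the model
assumptions, every tunable threshold with its default and rationale, the
synthetic-data generators and what passing tests do and do not certify,
and the package's numerical choices.
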