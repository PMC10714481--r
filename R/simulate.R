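# Shared internals for the summary-statistic generators -----------------

# Standardized-trait sampling SE of a per-allele beta:
# se = 1 / sqrt(2 n maf (1 - maf))
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Propagate direct (causal) per-allele effects into marginal per-allele
# effects through LD. Mixing happens on the standardized-genotype scale
# (marginal standardized effect = R %*% causal standardized effect), so a
# variant's marginal z can never exceed the causal variant's by an
# allele-frequency accident.
propagate_ld <- function(corr, beta_causal, maf) {
  s <- sqrt(2 * maf * (1 - maf))
  as.numeric(corr %*% (beta_causal * s)) / s
}

# Block-diagonal within-block correlation (constant rho), as a function
# mapping direct (causal) effects to marginal effects and giving the r2
# matrix clumping consumes.
ld_structure <- function(n_snps, block_size, rho, snp_ids) {
  if (block_size <= 1 || rho == 0) {
    corr <- diag(n_snps)
  } else {
    n_blocks <- ceiling(n_snps / block_size)
    block <- matrix(rho, block_size, block_size)
    diag(block) <- 1
    corr <- matrix(0, n_snps, n_snps)
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1) * block_size + 1):min(b * block_size, n_snps)
      corr[idx, idx] <- block[seq_along(idx), seq_along(idx)]
    }
  }
  dimnames(corr) <- list(snp_ids, snp_ids)
  corr
}

random_alleles <- function(n) {
  # non-palindromic pairs only, so harmonization is lossless by default
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  picks <- sample(length(pairs), n, replace = TRUE)
  list(
    ea = vapply(picks, function(i) pairs[[i]][1], character(1)),
    oa = vapply(picks, function(i) pairs[[i]][2], character(1))
  )
}

make_table <- function(snp, chrom, pos, ea, oa, eaf, truth, n) {
  se <- gwas_se(n, pmin(eaf, 1 - eaf))
  beta <- rnorm(length(truth), truth, se)
  tibble::tibble(
    snp = snp, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = z_to_p(beta / se),
    n = as.integer(n)
  )
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates exposure and outcome summary tables with the statistical
#' structure two-sample MR assumes: a spike-and-slab genetic architecture
#' in which instrument variants carry true exposure effects, outcome
#' effects equal to `theta` times the exposure effect plus optional
#' pleiotropy, sampling noise with the standardized-trait standard error
#' `1 / sqrt(2 n maf (1 - maf))` drawn independently for the two
#' (non-overlapping) samples, block-diagonal LD through which true
#' effects propagate into marginal effects (so clumping sees realistic
#' redundant signals), and optional reverse-causal variants whose primary
#' effect is on the outcome (the outcome-to-exposure path feeds back a
#' fraction `reverse_effect` of it), which Steiger filtering should
#' remove.
#'
#' Instrument effect sizes are drawn as per-variant exposure variance
#' explained uniform over `h2_snp_range`, whose defaults give strongly
#' significant, clearly valid instruments at biobank-scale sample sizes
#' (per-variant z around 10-30 at the default `n_exposure`).
#'
#' @param n_snps Total variants simulated.
#' @param n_instruments Variants with a true exposure effect.
#' @param theta True causal effect of exposure on outcome; default 0.15.
#' @param n_exposure,n_outcome Sample sizes; defaults 300,000 and
#'   500,000.
#' @param maf_range Uniform range of minor-allele frequencies.
#' @param h2_snp_range Uniform range of per-instrument exposure variance
#'   explained.
#' @param ld_block_size,ld_rho LD block size and constant within-block
#'   correlation (r, not r-squared); defaults 1 and 0 (unlinked).
#' @param pleiotropy `"none"`, `"balanced"` (direct outcome effects with
#'   mean zero on invalid instruments, inflating heterogeneity without
#'   biasing the slope), or `"directional"` (direct effects aligned with
#'   each invalid instrument's effect sign, so every invalid ratio
#'   estimate is pushed the same way and IVW is biased).
#' @param pleiotropy_sd Scale of the pleiotropic outcome effects:
#'   balanced draws `N(0, pleiotropy_sd^2)`; directional draws
#'   `sign(gamma) * U(0, 2 pleiotropy_sd)`.
#' @param prop_invalid Fraction of instruments given pleiotropic effects.
#' @param n_reverse Number of extra reverse-causal variants appended.
#' @param reverse_effect Outcome-to-exposure feedback coefficient for
#'   reverse variants; default 0.3.
#' @param outcome_type `"quantitative"` or `"binary"`; binary labels the
#'   outcome effects as log-odds and uses the effective sample size
#'   implied by `case_fraction` for the outcome SE.
#' @param case_fraction Case proportion for a binary outcome.
#' @param chrom,pos_start,pos_spacing Coordinates given to the variants.
#' @param seed Mandatory integer seed; the generator is deterministic
#'   given it.
#' @return A list: `exposure` and `outcome` summary tibbles, `ld` (the
#'   r-squared matrix), and `truth` (list of every latent quantity:
#'   per-variant causal and marginal effects, instrument / invalid /
#'   reverse ids, `theta`, mafs, analytic SEs).
#' @export
simulate_two_sample <- function(n_snps = 100L, n_instruments = 50L,
                                theta = 0.15,
                                n_exposure = 300000L, n_outcome = 500000L,
                                maf_range = c(0.05, 0.5),
                                h2_snp_range = c(5e-4, 3e-3),
                                ld_block_size = 1L, ld_rho = 0,
                                pleiotropy = c("none", "balanced",
                                               "directional"),
                                pleiotropy_sd = 0.02, prop_invalid = 0,
                                n_reverse = 0L, reverse_effect = 0.3,
                                outcome_type = c("quantitative", "binary"),
                                case_fraction = NULL,
                                chrom = "19", pos_start = 11200038L,
                                pos_spacing = 2000L, seed) {
  pleiotropy <- match.arg(pleiotropy)
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) abort("A seed is mandatory for the generator")
  if (n_instruments > n_snps) abort("n_instruments cannot exceed n_snps")
  if (n_instruments < 1) abort("The generator needs at least one instrument")
  if (prop_invalid < 0 || prop_invalid > 1) {
    abort("prop_invalid must lie in [0, 1]")
  }
  if (outcome_type == "binary" &&
      (is.null(case_fraction) || case_fraction <= 0 || case_fraction >= 1)) {
    abort("Binary outcomes need case_fraction in (0, 1)")
  }

  withr::with_seed(seed, {
    total <- n_snps + n_reverse
    snp <- sprintf("rs%06d", seq_len(total))
    pos <- pos_start + (seq_len(total) - 1L) * pos_spacing
    maf <- runif(total, maf_range[1], maf_range[2])
    al <- random_alleles(total)

    instr_idx <- seq_len(n_instruments)
    rev_idx <- if (n_reverse > 0) n_snps + seq_len(n_reverse) else integer(0)

    # causal (direct) exposure effects
    gamma <- numeric(total)
    h2 <- runif(n_instruments, h2_snp_range[1], h2_snp_range[2])
    gamma[instr_idx] <- sample(c(-1, 1), n_instruments, replace = TRUE) *
      sqrt(h2 / (2 * maf[instr_idx] * (1 - maf[instr_idx])))

    # pleiotropic direct outcome effects on a fraction of instruments
    alpha_pleio <- numeric(total)
    invalid_idx <- integer(0)
    if (pleiotropy != "none" && prop_invalid > 0) {
      n_invalid <- round(prop_invalid * n_instruments)
      invalid_idx <- sample(instr_idx, n_invalid)
      alpha_pleio[invalid_idx] <- if (pleiotropy == "balanced") {
        rnorm(n_invalid, 0, pleiotropy_sd)
      } else {
        # directional: every invalid instrument pushes its ratio estimate
        # the same way, so the offset is aligned with the instrument sign
        sign(gamma[invalid_idx]) * runif(n_invalid, 0, 2 * pleiotropy_sd)
      }
    }

    # reverse-causal variants: primary effect on the outcome, fed back
    # into the exposure through the outcome-to-exposure path
    delta_rev <- numeric(total)
    if (n_reverse > 0) {
      h2_rev <- runif(n_reverse, 3e-3, 8e-3)
      delta_rev[rev_idx] <- sample(c(-1, 1), n_reverse, replace = TRUE) *
        sqrt(h2_rev / (2 * maf[rev_idx] * (1 - maf[rev_idx])))
    }

    gamma_total <- gamma + reverse_effect * delta_rev
    alpha_total <- theta * gamma + alpha_pleio + delta_rev

    corr <- ld_structure(total, ld_block_size, ld_rho, snp)
    gamma_marginal <- propagate_ld(corr, gamma_total, maf)
    alpha_marginal <- propagate_ld(corr, alpha_total, maf)

    n_out_eff <- if (outcome_type == "binary") {
      # effective n of a case-control logistic GWAS
      round(n_outcome * case_fraction * (1 - case_fraction) * 4)
    } else {
      n_outcome
    }

    exposure <- make_table(snp, chrom, pos, al$ea, al$oa, maf,
                           gamma_marginal, n_exposure)
    outcome <- make_table(snp, chrom, pos, al$ea, al$oa, maf,
                          alpha_marginal, n_out_eff)
    outcome$n <- as.integer(n_outcome)

    list(
      exposure = exposure,
      outcome = outcome,
      ld = corr^2,
      truth = list(
        theta = theta,
        gamma = gamma, alpha = alpha_total,
        gamma_marginal = gamma_marginal,
        alpha_marginal = alpha_marginal,
        maf = maf,
        se_exposure = gwas_se(n_exposure, maf),
        instrument_snps = snp[instr_idx],
        invalid_snps = snp[invalid_idx],
        reverse_snps = snp[rev_idx],
        outcome_type = outcome_type,
        seed = seed
      )
    )
  })
}

#' Simulate a mediation chain of summary statistics
#'
#' Three summary tables over disjoint instrument sets for an exposure X
#' and a mediator M, with outcome Y receiving `theta_direct` from X
#' directly and `theta_my` from M: X instruments carry mediator effects
#' `theta_xm * gamma` and outcome effects
#' `(theta_direct + theta_xm * theta_my) * gamma`; M instruments carry no
#' exposure effect, mediator effects `gamma_m`, and outcome effects
#' `theta_my * gamma_m`. The implied total X-to-Y effect is
#' `theta_direct + theta_xm * theta_my` and the true proportion mediated
#' is carried in the truth record.
#'
#' @param n_x_instruments,n_m_instruments Instruments per trait.
#' @param theta_xm,theta_my,theta_direct True chain coefficients;
#'   defaults 0.5, 0.1, 0.15 (true proportion mediated 25%).
#' @param n_exposure,n_mediator,n_outcome Sample sizes (default 100,000
#'   each).
#' @inheritParams simulate_two_sample
#' @return A list of `exposure`, `mediator`, `outcome` tibbles and
#'   `truth` (chain coefficients, implied total, true proportion
#'   mediated, instrument ids).
#' @export
simulate_mediation_chain <- function(n_x_instruments = 30L,
                                     n_m_instruments = 30L,
                                     theta_xm = 0.5, theta_my = 0.1,
                                     theta_direct = 0.15,
                                     n_exposure = 100000L,
                                     n_mediator = 100000L,
                                     n_outcome = 100000L,
                                     maf_range = c(0.05, 0.5),
                                     h2_snp_range = c(5e-4, 3e-3),
                                     seed) {
  if (missing(seed)) abort("A seed is mandatory for the generator")
  withr::with_seed(seed, {
    total <- n_x_instruments + n_m_instruments
    snp <- sprintf("rs%06d", seq_len(total))
    pos <- 1000000L + (seq_len(total) - 1L) * 2000L
    maf <- runif(total, maf_range[1], maf_range[2])
    al <- random_alleles(total)

    x_idx <- seq_len(n_x_instruments)
    m_idx <- n_x_instruments + seq_len(n_m_instruments)

    draw_gamma <- function(idx) {
      h2 <- runif(length(idx), h2_snp_range[1], h2_snp_range[2])
      sample(c(-1, 1), length(idx), replace = TRUE) *
        sqrt(h2 / (2 * maf[idx] * (1 - maf[idx])))
    }
    gamma_x <- numeric(total)
    gamma_x[x_idx] <- draw_gamma(x_idx)
    gamma_m_direct <- numeric(total)
    gamma_m_direct[m_idx] <- draw_gamma(m_idx)

    beta_x <- gamma_x
    beta_m <- theta_xm * gamma_x + gamma_m_direct
    theta_total <- theta_direct + theta_xm * theta_my
    beta_y <- theta_total * gamma_x + theta_my * gamma_m_direct

    list(
      exposure = make_table(snp, "1", pos, al$ea, al$oa, maf, beta_x,
                            n_exposure),
      mediator = make_table(snp, "1", pos, al$ea, al$oa, maf, beta_m,
                            n_mediator),
      outcome = make_table(snp, "1", pos, al$ea, al$oa, maf, beta_y,
                           n_outcome),
      truth = list(
        theta_xm = theta_xm, theta_my = theta_my,
        theta_direct = theta_direct, theta_total = theta_total,
        proportion_mediated_pct = 100 * theta_xm * theta_my / theta_total,
        x_instruments = snp[x_idx], m_instruments = snp[m_idx],
        seed = seed
      )
    )
  })
}

#' Simulate a cis region under a named colocalization hypothesis
#'
#' Emits two traits' summary statistics over one region: under `"H4"`
#' both traits share a single causal variant; `"H3"` places distinct
#' causal variants in unlinked blocks; `"H1"` / `"H2"` give only one
#' trait a causal variant; `"H0"` leaves both null. Causal effect sizes
#' are set so the causal variant's expected |z| equals `z_causal` at the
#' given sample size, and effects propagate through within-block LD.
#'
#' @param scenario One of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param n_snps Region size; default 200.
#' @param n1,n2 Per-trait sample sizes; default 50,000.
#' @param z_causal Expected causal-variant |z|; default 12.
#' @inheritParams simulate_two_sample
#' @return A list of `trait1`, `trait2` tibbles and `truth` (scenario and
#'   causal variant ids).
#' @export
simulate_coloc_region <- function(scenario = c("H0", "H1", "H2", "H3", "H4"),
                                  n_snps = 200L, n1 = 50000L, n2 = 50000L,
                                  z_causal = 12,
                                  maf_range = c(0.05, 0.5),
                                  ld_block_size = 10L, ld_rho = 0.5,
                                  seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) abort("A seed is mandatory for the generator")
  withr::with_seed(seed, {
    snp <- sprintf("rs%06d", seq_len(n_snps))
    pos <- 11200038L + (seq_len(n_snps) - 1L) * 2000L
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    al <- random_alleles(n_snps)
    corr <- ld_structure(n_snps, ld_block_size, ld_rho, snp)

    pick_block <- function(exclude = integer(0)) {
      n_blocks <- ceiling(n_snps / ld_block_size)
      blocks <- setdiff(seq_len(n_blocks), exclude)
      b <- if (length(blocks) == 1) blocks else sample(blocks, 1)
      idx <- ((b - 1) * ld_block_size + 1):min(b * ld_block_size, n_snps)
      list(block = b, snp = if (length(idx) == 1) idx else sample(idx, 1))
    }

    causal1 <- NA_integer_
    causal2 <- NA_integer_
    if (scenario %in% c("H1", "H4")) {
      causal1 <- pick_block()$snp
    }
    if (scenario == "H2") causal2 <- pick_block()$snp
    if (scenario == "H4") causal2 <- causal1
    if (scenario == "H3") {
      c1 <- pick_block()
      c2 <- pick_block(exclude = c1$block)
      causal1 <- c1$snp
      causal2 <- c2$snp
    }

    causal_truth <- function(causal, n) {
      b <- numeric(n_snps)
      if (!is.na(causal)) {
        b[causal] <- z_causal * gwas_se(n, maf[causal])
      }
      propagate_ld(corr, b, maf)
    }
    trait1 <- make_table(snp, "19", pos, al$ea, al$oa, maf,
                         causal_truth(causal1, n1), n1)
    trait2 <- make_table(snp, "19", pos, al$ea, al$oa, maf,
                         causal_truth(causal2, n2), n2)
    list(
      trait1 = trait1, trait2 = trait2,
      truth = list(
        scenario = scenario,
        causal_trait1 = if (is.na(causal1)) NA_character_ else snp[causal1],
        causal_trait2 = if (is.na(causal2)) NA_character_ else snp[causal2],
        z_causal = z_causal, seed = seed
      )
    )
  })
}

#' Write simulated tables in the dialect the readers consume
#'
#' @param sim A list from one of the generators.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly. Summary tables become TSV, the LD
#'   matrix (if any) a square TSV, and the truth record JSON.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(sim), c("ld", "truth"))) {
    readr::write_tsv(sim[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  if (!is.null(sim$ld)) {
    write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
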