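---
title: "Drug-target Mendelian randomization with targetmr: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The model

Two-sample Mendelian randomization treats a genetic variant $j$ as an
instrumental variable for an exposure $X$ (here: a circulating lipid, or
the expression of a drug-target gene). From two non-overlapping GWAS we
observe the variant's association with the exposure,
$\hat b_{Xj} \sim N(b_{Xj}, \sigma_{Xj}^2)$, and with the outcome,
$\hat b_{Yj} \sim N(b_{Yj}, \sigma_{Yj}^2)$. If the variant is a valid
instrument — associated with $X$ (relevance), independent of confounders
(independence), and affecting $Y$ only through $X$ (exclusion
restriction) — then $b_{Yj} = \theta\, b_{Xj}$ and each variant supplies a
ratio estimate $\hat\theta_j = \hat b_{Yj} / \hat b_{Xj}$.

The inverse-variance weighted (IVW) estimator pools the ratios with
weights $w_j = b_{Xj}^2/\sigma_{Yj}^2$, equivalently a weighted regression
of $\hat b_Y$ on $\hat b_X$ through the origin. It is the main analysis;
the sensitivity estimators relax different instrument assumptions:

* **MR-Egger** adds an intercept: its slope is consistent under
  directional pleiotropy if instrument strength is independent of the
  pleiotropic effects (InSIDE), and the intercept estimates the average
  directional pleiotropy. Variants are first oriented so $b_{Xj} \ge 0$,
  which makes the fit invariant to arbitrary allele coding.
* **Weighted median** is consistent while valid instruments carry more
  than half the weight.
* **Weighted mode** is consistent if the largest group of variants
  sharing one ratio is valid.
* **Profile maximum likelihood** models the exposure-side noise
  explicitly: profiling the latent instrument effects out of the
  bivariate normal likelihood leaves
  $\ell(\theta) = -\tfrac12\sum_j (\hat b_{Yj} - \theta \hat b_{Xj})^2 /
  (\sigma_{Yj}^2 + \theta^2 \sigma_{Xj}^2)$, maximized numerically from
  the IVW start; its $\sigma_X \to 0$ limit is exactly fixed-effect IVW.
* **Multivariable MR** regresses the outcome betas on several exposures'
  beta vectors jointly (no intercept, weights $1/\sigma_Y^2$), giving each
  exposure's direct effect conditional on the others.

In drug-target mode the instruments are cis variants of the gene encoding
the target protein, so $\theta$ is interpreted as the effect of
pharmacologically modulating that target by one unit of its proxy lipid.

### The sign convention

The single most consequential convention in a drug-target analysis is the
direction of the exposure. `run_drug_target_mr()` reports effects **per
unit of lipid lowering** — the direction of drug action — by negating the
per-unit-increase estimate (`effect_direction = "raising"` disables
this). A positive lifespan estimate therefore reads "lowering the lipid
through this target extends lifespan". Because every estimator is
equivariant under jointly recoding a variant's alleles, this convention is
independent of how the input files code their effect alleles; a test
verifies that flipping the coding of the whole exposure file changes
nothing.

## Harmonization rules

Outcome records are aligned to the exposure's effect allele: identical
alleles pass through; swapped alleles negate the outcome beta and reflect
its frequency; strand-complement codings are complemented first; anything
else is strictly excluded. Palindromic variants (A/T, G/C) carry no
strand information in their allele labels, so orientation is inferred from
allele frequencies: same side of 0.5 keeps the coding, opposite sides flip
it, and any frequency inside `[0.42, 0.58]` (or missing) drops the
variant as unresolvable. The 0.42 window is a package default exposed as
`palindrome_eaf_window`; it follows common two-sample MR practice, and the
harmonization report records every drop with its reason so the choice is
auditable. Variants absent from the outcome file are dropped rather than
proxied — LD-proxy search would require a reference panel this package
deliberately does not ship.

## Instrument selection defaults

| Setting | Default | Where | Why |
|---|---|---|---|
| significance | `p ≤ 5e-8` | all selection | genome-wide convention |
| genome-wide clumping | `r² < 0.001`, 10,000 kb | lipid instruments | near-independence for polygenic exposures |
| cis clumping | `r² < 0.3`, ±100 kb | drug-target instruments | cis regions hold few independent signals; liberal threshold retains power, with `r² ∈ {0.3, 0.1, 0.01, 0.001}` rerun as a sensitivity grid |
| eQTL instruments | ±1 Mb, MAF > 0.01, BH-FDR < 0.05, `r² < 0.3` | expression exposures | standard cis-eQTL window and filters |
| minimum instruments | 2 | per target | below this a target is flagged `insufficient_ivs`, not analyzed |
| weak instruments | `F < 10` | diagnostics | conventional weak-instrument boundary |

Clumping is greedy on ascending p-value with ties broken by variant id,
so results are invariant to input row order. Pairs absent from the
user-supplied LD matrix are treated as unlinked with a warning — the
matrix is user responsibility, and silently treating absence as linkage
would discard instruments irrecoverably.

Steiger filtering removes variants whose outcome variance explained,
$r^2 = t^2/(t^2 + n - 2)$, exceeds their exposure variance explained —
the signature of reverse causation. The default is the strict inequality;
`mode = "ztest"` removes only variants whose reversal is significant under
a one-sided Fisher-z comparison, for users who prefer to retain ambiguous
variants. Per-variant variance explained for the F statistic uses the same
$t^2$ convention by default, with the standardized-trait alternative
$2\,\mathrm{eaf}(1-\mathrm{eaf})\,b^2$ selectable.

## Diagnostics, power, and pooling

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ uses the
first-order ratio weights and a $\chi^2_{k-1}$ reference; the Egger
intercept test uses a $t_{k-2}$ reference with multiplicative
overdispersion floored at 1, so heterogeneity can widen but never narrow
intervals. Leave-one-out flags a variant when omitting it flips
significance at 0.05 or moves the estimate by more than one pooled
standard error.

Power uses the non-centrality approximation
$\Phi(-z_{1-\alpha/2} + |\theta|\sqrt{nR^2v})$ for unit-variance traits,
with $v = \mathrm{cf}(1-\mathrm{cf})$ for a binary outcome with case
fraction cf — the standard summary-data approximation for two-sample MR
power calculators.

Estimates of one trait from several consortia are pooled by
inverse-variance fixed effects, switching to DerSimonian–Laird random
effects when the across-study heterogeneity test has `p < 0.10` (the
`rule = "auto"` default; the threshold is configurable because no single
convention exists). The computation is delegated to `metafor`. FDR
families are explicit: `run_drug_target_mr()` adjusts the main IVW
p-values across the targets analyzed against one outcome dataset, and
`bh_fdr()` adjusts exactly the vector it is given, never an implicit
family.

## Mediation

The two-step decomposition takes the exposure-to-mediator estimate
$\beta_A$, the exposure-adjusted mediator-to-outcome estimate $\beta_B$,
and the total effect $\beta_C$: the indirect effect is
$\beta_A\beta_B$, the direct effect is $\beta_C - \beta_A\beta_B$ (so
direct + indirect = total holds to machine precision by construction),
and the proportion mediated is their ratio, reported as a percentage.
The indirect-effect SE is the product delta method
$\sqrt{\beta_A^2\sigma_B^2 + \beta_B^2\sigma_A^2}$; the proportion's CI is
delta-method rather than bootstrap for determinism, and a flag marks
decompositions whose total-effect CI spans zero, where the proportion is
unstable. In `run_mediation_pipeline()` step two adjusts for the exposure
by multivariable MR over the union of both instrument sets — the standard
two-step construction; an unadjusted IVW option exists. Binary mediators
are carried on the log-odds scale through the product, a documented
approximation. A worked decomposition from a reported pair (total 0.164,
direct 0.127) gives indirect 0.037 and proportion 22.6%; a published
analysis printing 22.8% from unrounded inputs is consistent with these
rounded ones.

## Colocalization

For each variant and trait the Wakefield log approximate Bayes factor is
$\tfrac12[\log(V/(V+W)) + z^2W/(V+W)]$ with $V$ the squared SE and $W$
the prior effect variance. Under one causal variant per trait, the five
hypothesis posteriors follow from per-variant priors
$p_1 = p_2 = 10^{-4}$ and shared prior $p_{12} = 10^{-5}$ (standard
defaults, configurable); $W$ defaults to $0.15^2$ for quantitative traits
and $0.2^2$ on the log-odds scale for binary ones. All accumulation uses
log-sum-exp; the H3 term $\sum_{j\ne l}$ is computed as a log-space
difference, and a dedicated test checks agreement with direct enumeration
on small regions to $10^{-10}$. `PP.H4 > 0.85` flags strong
colocalization. Single-causal-variant colocalization only; multi-signal
decomposition is out of scope.

## What the synthetic generators emulate

`simulate_two_sample()` draws per-variant minor-allele frequencies
uniformly on `[0.05, 0.5]`, gives instruments per-variant exposure
variance explained uniform on `[5e-4, 3e-3]` (per-variant z of roughly
10–30 at biobank sample sizes, matching strong lipid cis signals), and
adds sampling noise with the standardized-trait SE
$1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ independently in the two
samples. Defaults of `n_exposure = 300000` and `n_outcome = 500000`
mirror the scale of consortium lipid GWAS and the largest lifespan GWAS
(about 500,000 individuals); the binary-outcome mode mimics a
case-control longevity design through the effective-sample-size
approximation $4n\,\mathrm{cf}(1-\mathrm{cf})$.

LD is block-diagonal with constant within-block correlation, and causal
effects propagate into marginal effects on the standardized scale
($E[z_{\text{marginal}}] = R\, z_{\text{causal}}$), so clumping sees
realistic redundant signals and no LD partner can out-signal its causal
variant by an allele-frequency accident. Balanced pleiotropy adds
mean-zero direct outcome effects (heterogeneity without slope bias);
directional pleiotropy aligns each invalid instrument's direct effect
with its instrument sign, so all invalid ratio estimates push the same
way — the regime that biases IVW and that the weighted median resists.
The default pleiotropy scale (0.02 on the outcome-beta scale, roughly
2.5 times the per-variant causal signal) makes invalid instruments
clearly invalid. Reverse-causal variants have their primary effect on the
outcome, fed back into the exposure with coefficient 0.3, giving them the
variance-explained signature Steiger removes.

What the generators do **not** emulate: sample overlap between the two
GWAS, population stratification, winner's-curse selection of instruments,
assortative mating, misreported allele codings beyond strand flips, and
real LD structure (blocks are idealized). Passing closed-loop tests
therefore certifies the statistical machinery under its stated
assumptions, not robustness to these real-data pathologies.

## Numerical choices

* Bootstrap SEs (median/mode) are parametric, redrawing betas from their
  reported normals; 1000 replicates by default; seeds are explicit
  arguments and never touch the caller's RNG state.
* The weighted-mode bandwidth is the modified Silverman rule
  $0.9\,\min(\mathrm{sd}, \mathrm{mad})\,k^{-1/5}$ scaled by `phi`
  (default 1), with a guard for zero spread.
* Maximum likelihood uses BFGS on the one-dimensional profile with the
  observed-information SE; non-convergence raises an error carrying the
  optimizer code rather than returning a silent fallback.
* Perfect-fit regressions (zero residual dispersion) return the
  dispersion-free WLS standard errors; the multiplicative overdispersion
  factor is floored at 1 everywhere.
* Ratio-estimate SEs default to the first-order delta method (simple
  weighting); second-order is available where exposure-side noise
  matters.
* Ties in clumping break on variant id; all generators require an
  explicit seed and are bit-reproducible given it.

## Problem sizes used by the validation suite

The statistical acceptance checks use 500 replicates for IVW recovery
and coverage (50 instruments, n = 300k/500k), 1000 for the Egger
intercept size, 200 for weighted-median robustness and mediation-chain
recovery, and 100 per colocalization scenario — sizes at which the
Monte-Carlo error of each checked quantity is several times smaller than
its acceptance margin, while the whole suite runs in about a minute on
one core.

## Known limitations

* No LD-proxy lookup for variants missing from the outcome GWAS.
* No liftover: all coordinates are GRCh37, 1-based inclusive.
* Binary-trait effects are treated as log-odds ratios throughout,
  including inside mediation products — an approximation that ignores
  non-collapsibility.
* Single-causal-variant colocalization only.
* The LD matrix is user-supplied; the package neither computes LD from
  genotypes nor queries remote LD services.
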