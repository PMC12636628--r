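---
title: "Methods: sex-biased locus discovery and gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased locus discovery and gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sexloci)
```

This vignette documents the statistical models behind `sexloci`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design
was genuinely open.

## 1. Summary-statistics model

The atomic unit is a per-variant association record: effect allele,
log-odds effect `beta`, standard error `se`, p-value, effect-allele
frequency, sample size, imputation quality. Three transformations
prepare cohort-level records for meta-analysis:

- **LMM rescaling.** Case-control GWAS fit with linear mixed models
  estimate effects on the observed 0/1 scale. `rescale_lmm_to_logistic()`
  divides `beta` and `se` by `mu(1-mu)`, `mu` the sample case fraction.
  The z-score is invariant, which the tests assert to 1e-12.
- **Effective sample size.** `effective_sample_size()` returns
  `4 N v (1-v)`; for proxy-phenotype cohorts (case status inferred from
  parental disease) the result is divided by 4. The bare expression
  `4 v (1-v)` without `N` is not a sample size; the only reading
  consistent with sample-size magnitudes is `4 N v(1-v)`, which is what
  is implemented.
- **Allele harmonization.** Records are matched to a reference allele
  pair by effect/other swap, then strand complement. Palindromic (A/T,
  C/G) variants with EAF in [0.4, 0.6] cannot be oriented reliably and
  are dropped rather than guessed; the drop is logged.

Fixed-effects meta-analysis is inverse-variance weighting; random
effects use the DerSimonian–Laird moment estimator
`tau² = max(0, (Q-(k-1))/(S1 - S2/S1))`. With homogeneous inputs the
random-effects result reduces exactly to the fixed-effects one, and its
standard error can never be smaller — both are tested, and the
estimates are cross-checked against an independent meta-analysis
package (`metafor`) when available.

P-values are computed from z-scores through log-scale survival
functions, so `-log10 p` stays finite past the double-precision
underflow near `p = 1e-308` (Miami plots truncate at `1e-30`, but
storage must not overflow).

## 2. Sex heterogeneity

`sex_heterogeneity_test()` computes
`z = (b_F - b_M)/sqrt(se_F² + se_M² - 2 rho se_F se_M)`. The default
`rho = 0` reflects disjoint female and male strata; the parameter is
exposed because meta-analysis tooling supports overlap correction, and
whether any overlap term should apply to a given design is a property
of that design, not of the test. The cross-sex effect ratio
`max(|b_F|,|b_M|)/min(|b_F|,|b_M|)` is computed on the log-odds scale;
when the effects have opposite signs the magnitude ratio is still
reported, and a zero denominator yields `Inf` (recorded, not dropped).

Type-I error of the test under a shared-effect null is part of the
acceptance surface: with 2,000 variants at an effective `n` of 20,000
per stratum the empirical rejection rate at `alpha = 0.05` must fall
in the binomial band [0.040, 0.060].

## 3. Locus discovery

Candidate loci are formed by transitive 1 Mb chaining of variants with
`p < 1e-5` ("sliding window" with merge-interval semantics — window
anchoring is otherwise undefined). Within each candidate locus, greedy
LD clumping by ascending p-value at `r² < 0.01` yields independent
signals; p ties break to the lower (chromosome, position) so output is
deterministic and row-order invariant. A signal survives when its lead
is genome-wide significant (`p < 5e-8`) in one sex with nominal
heterogeneity (`p_het < 0.05`), or when the heterogeneity test itself
reaches `5e-8` (the het-GWAS route). Signals in LD (`r² > 0.01`,
MAF > 1%) with a cataloged variant that is more significant in the same
sex but not itself heterogeneous are removed; one signal per locus is
kept. The APOE-like region (±5 Mb, configurable) is masked before
clustering.

The published analysis observed, rather than enforced, that retained
leads had cross-sex ratios ≥ 1.5; accordingly the default behaviour is
assert-and-warn, with `ratio_hard = TRUE` available to make it a
filter. Known-variant exclusion needs the catalog's own heterogeneity
p-values; when absent the rule cannot fire and a warning is logged.
Novelty is classified by distance then LD (>1 Mb: novel locus; <1 Mb
and `r² < 0.01`: novel variant at a known locus; otherwise known
variant), with a manual override list for variants later shown to be
independent signals.

## 4. PWAS

`train_weights()` residualizes protein abundance on covariates, screens
for SNP-based signal with a permutation p-value of the cross-validated
predictive r² of the best marginal variant (200 permutations by
default; genes with `p >= 0.01` fail), then fits four models — top1,
lasso, elastic net (alpha = 0.5) and ridge — choosing by 5-fold CV r².
Ridge serves as the dense BLUP-like model; a sparse Bayesian mixed
model would occupy the same niche but adds an MCMC dependency without
changing the screening role, which is a deliberate substitution. The
permutation screen likewise replaces variance-component REML: it tests
the same null (no genetically predictable abundance) at a fraction of
the cost.

`pwas_assoc()` computes the weighted burden `z = w'z/sqrt(w'Rw)` over
the variants shared between model and GWAS. R is shrunk toward the
identity (`lambda = 0.1`) and eigenvalue-floored to positive definite;
genes retaining less than half their absolute weight mass (coverage
floor 0.5) are refused rather than silently extrapolated. FDR is
Benjamini–Hochberg within each GWAS × weights × tissue combination (a
pooled mode is available; the per-combination reading matches the
definition of significance "for every combination").

Sex-bias classification: a protein is female-biased if FDR-significant
with female GWAS × female weights (primary) or female GWAS × combined
weights (secondary), and every male-GWAS run is direction-discordant or
`p > 0.05`; symmetric for males; and a locus whose most significant
protein is not sex-biased has all its proteins demoted. Cross-ancestry
consistency uses the sample-size-weighted z meta-analysis and requires
the discovery-sex p to improve while the opposite sex stays above 0.05;
the proxy-exclusion sensitivity rule requires concordant direction with
`p < 0.05` and opposite-sex `p > 0.05`.

## 5. Colocalization, SMR and the HEIDI-style check

Per-variant Wakefield log-ABFs (`wakefield_labf()`) use prior effect
SDs of 0.2 for quantitative traits and 0.15 log-odds for case-control
traits — the conventional defaults — and the five single-causal-variant
hypotheses are summed in log space (`logsum`/`logdiff`), which the
tests verify against direct exhaustive enumeration on 5-SNP loci to
1e-10. Priors default to `p1 = p2 = 1e-4`, `p12 = 1e-5`. The
adjusted-prior pass raises `p12` to `5e-5`; the exact elevated value
used in the published analysis is unstated, so ours is an explicit,
configurable choice recorded on every result, and in `"best"` mode the
larger PP4 wins, with the mode recorded. Multi-signal (SuSiE-style)
colocalization is out of scope; loci suspected of multiple signals are
examined through per-window runs around alternative index variants, as
the multi-tag plots do.

SMR uses the Wald ratio and
`z² = z_g² z_q²/(z_g² + z_q²) ~ chi²(1)`. The instrument-heterogeneity
check is deliberately named `heidi_like`: instruments are cis-QTL
variants with `p < 1.6e-3` and `0.05 < r² < 0.9` to the top instrument
(at most 20); Wald-ratio differences from the top instrument get
delta-method variances and LD-derived covariances, and the sum of
squared standardized differences is referred to a Satterthwaite-matched
scaled chi-square rather than the original saddlepoint approximation.
This simplification preserves the operating characteristics that matter
(retaining ≥ 80% of single-causal loci at `p > 0.05`, flagging ≥ 70% of
two-causal loci) and is what the acceptance checks measure.

## 6. Gene prioritization

The 1/2/3 score is a pure function of a per-gene evidence ledger; all
rule branches are enumerated in a table-driven test. Two readings
required a decision:

- "More than one gene-specific QTL colocalization across different
  tissues or datasets" counts distinct (QTL type, dataset) pairs, so
  two datasets of the same tissue count separately.
- "Sex-biased differential abundance across cases and controls" is
  modeled as a sex × status interaction (`protein ~ sex * status +
  covariates` restricted to biomarker-defined A-T-/A+T+ subjects); a
  per-sex-contrast mode exists for the alternative reading. The sex
  main effect comes from `protein ~ sex + diagnosis + covariates` over
  all subjects. Cells with fewer than 10 subjects skip the interaction
  analysis with a log entry.

Methylation/histone/chromatin QTLs never count toward gene-specific
scoring (they are locus-level epigenetic evidence, not gene
assignments). Literature/missense overrides force score 1 with recorded
provenance; excluded loci are dropped entirely. Monotonicity — adding a
strong colocalization never worsens a score — is property-tested on
1,000 random ledgers.

## 7. Enrichment

Hypergeometric upper-tail tests with BH correction across sets; the
gene-ratio denominator is the number of query genes mapped to the
universe (the convention of the standard enrichment tooling — fold
filters depend on it, hence documented). The sex-specificity filter
keeps a set for one sex when FDR-significant and its gene ratio is at
least 1.5× the other sex's; a set absent from the other sex is treated
as ratio 0 and therefore passes the fold test — the source analysis is
silent here, and the convention is switchable. Cell-type specificity
assigns a gene to its predominant type when that type's share of summed
mean expression is ≥ 1.5× the runner-up; types with fewer than 10
annotated genes across both sex lists are flagged unreliable. The drug
pipeline is fully file-based (PPI edges, literature flags, druggable
tiers, FDA list, GMT drug sets): expansion keeps PPI neighbors of seeds
that are literature-flagged and tier-1 druggable, with per-gene
provenance.

A note on fold definitions: a fold-enrichment below 1 alongside
claimed over-representation appears in the source material for one cell
type; our fold is strictly `(k/n)/(K/N)` and we document rather than
imitate the discrepancy.

## 8. Structural-variant locus dissection

`cubex_ld()` estimates the haplotype frequency of two unphased
biallelic markers from the 3×3 genotype table. The EM stationarity
condition is a cubic in `f_AB`; its coefficients are recovered exactly
by evaluating the defining polynomial at four points and solving the
Vandermonde system, avoiding hand-expanded coefficient algebra. All
real roots in `[max(0, p+q-1), min(p,q)]` are scored by multinomial
likelihood (the root count is reported); when no valid root is found
numerically, EM is the fallback. Exact equality with direct haplotype
counting holds whenever there are no double heterozygotes, and
agreement with the EM fixed point to 1e-6 is asserted over 1,000
random tables.

The SV is modeled as a biallelic dosage 0/1/2; a nested sub-haplotype
can be represented as a second biallelic marker tagged the same way.
Tag SNVs with cubic-Hill `r² > 0.1` form the imputation panel, ordered
by r². The imputer is a polynomial-kernel (degree 3) support-vector
classifier evaluated over repeated stratified 70/30 train/test splits —
we read the "100 permutations" of the published pipeline as 100
repeated random splits (a label-permutation null is available
separately as the shuffled-label baseline check), and the contract is
the accuracy-vs-LD relationship, not a specific margin algorithm.
Missing genotypes are pairwise-complete for LD and mean-imputed for
classifier features.

Conditional association refits the variant's model with the (imputed)
SV dosage as a covariate; variant/condition pairs with `r² > 0.99` are
reported non-estimable rather than silently dropped. The locus pheWAS
applies MAC ≥ 10 and missingness ≤ 0.1 filters and a per-tissue
Bonferroni threshold of `0.05 / #aptamers`.

## 9. The synthetic-data generator

LD is generated by a block copula: latent Gaussians follow a
first-order autoregression within a block and are thresholded at the
allele-frequency quantile. The latent correlation is calibrated
numerically (1-D quadrature of the bivariate-normal orthant mass plus
root finding) so the *binary* adjacent-variant correlation equals the
requested `within_block_r`. Allele frequencies are drawn once per
block: variants in strong LD have similar frequencies in real data, and
equal frequencies keep any requested correlation feasible for binary
variables. This exercises clumping and colocalization correctly and is
orders of magnitude faster than coalescent simulation, but it does not
produce realistic human LD decay, allele-frequency spectra,
relatedness, or imputation-quality structure — so passing tests show
the *rules and statistics* behave correctly, not that power estimates
transfer to real cohorts.

Case-control GWAS can be generated two ways: individual-level logistic
fits (exact; used at small n) and an asymptotic summary-statistic
approximation — marginal effects from LD-weighted planted effects, the
logistic score standard error `1/sqrt(2 f(1-f) N_eff)`, and normal
noise — validated against the fit mode. Proxy cohorts halve planted
effects (a single-transmitting-parent heuristic; the published analysis
states only the `N_eff/4` weighting, so the factor 2 on beta is this
package's configurable stand-in, not a literature claim) and carry
`N_eff/4`. Two APOE-like dosage covariates with configurable effects
enter the logistic mode.

The SV fixture generates the SV and its tags jointly on phased
haplotypes with per-tag target r² (tags conditionally independent given
the SV), enforcing the frequency feasibility bound
`r²_max = min(p(1-q)/(q(1-p)), q(1-p)/(p(1-q)))` with an error naming
the bound. The default geometry used in the end-to-end dissection
checks — tag r² of 0.97/0.75/0.27 plus seven additional tags between
0.35 and 0.9, SV frequency 0.4, n = 3,500 — mirrors the multi-SNV
consensus-panel setting of the motivating case study (a ~20-SNV
consensus panel, an SV allele near 40% frequency, and a pQTL cohort of
~3,500).

## 10. Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to make each property
statistically decisive while keeping a full run near half a minute:
2,000 variants at stratum `N_eff` 20,000 for heterogeneity calibration;
20 genome simulations of 22 LD blocks (10 biased at ratio 2.0, 10
unbiased, 2 null) with 50,000-sample cohorts for locus recovery; 200
active plus 200 null genes for the PWAS oracle; 100 replicates each for
shared/distinct colocalization and homogeneous/heterogeneous
instrument sets; 1,000 random tables for the cubic-vs-EM agreement; 50
replicates for the SV dissection.

Numerical conventions: hypothesis sums in log space; LD matrices shrunk
toward identity before inversion-free quadratic forms; eigenvalue
floors at 1e-8; permutation p-values computed as `(1+b)/(1+B)` so they
are never zero; clumping ties broken by genomic position; genomic
coordinates 1-based inclusive everywhere except BED interchange. All
generators accept a single integer seed, and derived sub-seeds
(`child_seed()`) stay below 2^31. A full pipeline rerun under the same
seeds is byte-identical, which the bundle checksums make checkable.

## Known limitations

- Single-causal-variant colocalization only; closely spaced multiple
  signals at one locus deflate PP4 (mitigated, not solved, by
  alternative-index windows).
- The HEIDI-style test's Satterthwaite matching is slightly
  conservative relative to the saddlepoint original at extreme LD.
- The synthetic genome has no allele-frequency/LD realism (above), no
  genomic-control or LDSC-intercept machinery, and no sample-overlap
  estimation — all declared out of scope.
- Drug/literature/PPI resources are consumed as files; no live
  database queries are made, so results are only as current as the
  supplied tables.
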