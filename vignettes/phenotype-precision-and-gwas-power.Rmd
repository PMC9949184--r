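---
title: "Phenotype measurement precision and GWAS power: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype measurement precision and GWAS power: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopower)
```

## The question the package answers

Quantitative phenotypes in biobank-scale genetics are increasingly measured
by automated pipelines — for example left-ventricular ejection fraction
(LVEF, in %) derived from cardiac MRI without manual quality control. Such
measurements carry error, and measurement error attenuates every per-variant
association statistic. phenopower quantifies that cost in the currency
geneticists actually budget in: **how many samples is a percentage point of
measurement error worth?**

The machinery is a simulation study. A cohort with a known additive genetic
architecture is generated; the phenotype is degraded in controlled ways
(additive Gaussian noise of increasing SD, rounding to the nearest 5 as in
visual reads, or a sex-specific normal/abnormal dichotomisation); the same
covariate-adjusted association scan is run on every version; and the
degraded scans are scored against the undegraded baseline scan. A parallel
sweep randomly shrinks the cohort instead. Two linear models — power metric
on phenotype mean absolute error (MAE), and power metric on percent of the
cohort retained — then yield an *equivalence ratio*: the cohort reduction
with the same effect as a 1% MAE increase.

## The association model

For each variant $j$ with alt-allele dosage $g_{ij} \in [0,2]$, the scan
fits, by ordinary least squares,

$$ y_i = \beta_0 + \beta_a\,\mathrm{age}_i + \beta_s\,\mathrm{sex}_i +
   \beta_j\, g_{ij} + \varepsilon_i, $$

and reports $\hat\beta_j$, its standard error, the $t$ statistic and the
two-sided p-value on $n_j - 4$ degrees of freedom, where $n_j$ counts the
samples with a non-missing dosage (per-variant complete-case analysis; no
mean imputation). Genome-wide significance uses the conventional
$p < 5\times10^{-8}$, strictly.

Implementation notes that matter for correctness:

* The covariates are projected out of the phenotype and of all complete
  dosage columns once (QR residualisation), after which each variant is a
  simple regression on residuals — algebraically identical to the full OLS
  fit but $O(nm)$. The unit suite checks agreement with a direct
  normal-equations solve to 10 significant digits.
* p-values are computed in log space (`pt(..., log.p = TRUE)`), so scans
  with $p \ll 10^{-300}$ still order correctly through the `log10_p`
  column; the linear `p` column is floored at the smallest positive double.
* Monomorphic variants are reported with `NA` effects and a `degenerate`
  flag rather than dropped, and can never enter a significant set.
* Binary (0/1) traits are scanned with the same linear engine by default,
  which mirrors common biobank practice and keeps every degradation
  comparable within a single engine; a per-variant logistic fit is
  available via `engine = "logistic"`.

## Quality control

Defaults follow standard biobank GWAS filters: sample call rate
$\ge 0.98$; then minor allele frequency $\ge 0.01$, call rate $\ge 0.95$
for genotyped variants or INFO $\ge 0.3$ for imputed variants, and exact
Hardy–Weinberg equilibrium $p \ge 10^{-20}$. Rules are applied in that
order and each variant is tallied against the first rule it fails, so the
report reconciles exactly.

At a floor of $10^{-20}$ a chi-square HWE test is numerically meaningless,
so the package implements the exact conditional test: the distribution of
the heterozygote count given the allele counts, with the p-value summing
all configurations no more probable than the observed one (no mid-p
correction). Probabilities are built by the upward recurrence over
heterozygote counts entirely in log space and normalised by log-sum-exp;
the suite verifies it against an independent closed-form enumeration for
all totals up to 200. HWE is computed on hard-called genotypes (nearest
integer), since dosage-based HWE is not well defined.

## Locus detection and the two power metrics

Significant SNPs are clustered into loci per chromosome by single-linkage
agglomeration of base-pair positions cut at a merge distance (default 1
Mb). On one-dimensional positions this is exactly "split the sorted
positions at gaps larger than the cutoff", the classic distance clumping;
we chose single linkage because it is the only standard linkage for which
the hierarchical formulation reduces to that field-standard behaviour. A
brute-force connected-components oracle backs the tests.

Two metrics score a degraded scan against the baseline:

* **SNP accuracy** $= TP/(TP+FP+FN)$ over the two significant-SNP sets
  (the Jaccard index), with SNP identity the canonical
  `chrom:pos:ref:alt` string.
* **Loci sensitivity** $=$ peaks\_correct / peaks\_base, where a baseline
  locus persists if a degraded locus interval overlaps it after both are
  extended by half the merge distance. Persistence is interval-based, not
  lead-SNP identity, so a lead that shifts to an LD partner still counts.

Empty-set conventions: when both significant sets are empty, and when the
baseline has no loci, the metrics are defined as 1 — a no-signal baseline
compares as "nothing lost". The study design never reaches these cases
(the baseline is constructed to have signal), but degenerate inputs should
not produce NaNs.

## The synthetic cohort

`simulate_genotypes()` builds diploid dosages from two haplotypes per
sample. Within an LD block, a haplotype allele copies the previous
variant's allele with probability `ld_rho` and is otherwise a fresh
Bernoulli draw. All variants in a block share one allele frequency, drawn
uniformly from `maf_range`: under the copying process a constant
within-block frequency is what makes the adjacent-dosage correlation equal
`ld_rho` exactly while keeping every variant's frequency on target.
Blocks are independent, laid out contiguously over 22 chromosomes at 5 kb
spacing. Missing calls are injected at random; imputed status is assigned
per variant (default 90%) with INFO drawn from Beta(10, 0.5), so QC has
realistic attributes to act on.

`simulate_phenotype()` draws the trait as
mean $+$ genetic component $+$ covariate component $+$ Gaussian residual.
Defaults emulate an LVEF-like trait in a middle-aged imaging cohort: mean
55.4%, SD 6.78%, age $\sim N(54.9, 7.47^2)$ years, 47.8% male, with small
negative age ($-0.05$ %/year) and male ($-2$%) effects — covariate shares
of a few percent of variance, enough for the adjustment to matter without
dominating. Causal variants (default 5) are placed one per equal-width
stratum of the panel, drawn from the middle half of each stratum so
consecutive causal variants are at least half a stratum apart and found
distinct loci. Components are empirically rescaled, and the residual is
orthogonalised against the realised genetic and covariate components, so
the realised heritability and total SD match their targets almost exactly
rather than only in expectation.

What the generator does *not* emulate: long-range LD and the real
chromosome-scale LD landscape (blocks are independent and short), allele
frequency–effect size coupling, population structure, relatedness, and
imputation error that correlates with INFO. Passing tests therefore show
that the *pipeline machinery* behaves correctly and that the
noise-vs-cohort trade-off has the expected structure on a clean additive
architecture — not that the fitted slopes transfer numerically to any real
cohort.

## The degradations and the sweeps

* **Gaussian noise**, SD $\sigma \in \{1,\dots,10\}$ by default. Each level
  is an *independent* draw (fresh seed per level), not a cumulative path:
  independence makes the levels exchangeable and is the conventional
  reading of "gradually incrementing noise". For a level $\sigma$ the
  expected MAE is $\sigma\sqrt{2/\pi}$ and the expected squared correlation
  with the original is $\mathrm{var}(y)/(\mathrm{var}(y)+\sigma^2)$; with
  the default trait SD 6.78 and $\sigma = 5$ these give 3.99% and 0.648.
  Degraded values are deliberately *not* clamped into (0, 100); a `clamp`
  flag exists but defaults off, since clamping would distort the noise
  model at the tails.
* **Rounding to the nearest 5**, ties away from zero (57.5 → 60). The
  rounding convention is fixed and documented because printed cohort
  tables in the wild are frequently inconsistent about halves.
* **Binarization** to normal/abnormal with inclusive sex-specific normal
  ranges, 52–72% (male) and 54–74% (female), encoded 0 = normal,
  1 = abnormal. Records with an unknown sex level are set `NA` and counted
  in a warning rather than guessed.
* **Cohort downsampling** retains `round-half-away(fraction × n)` samples
  uniformly at random, *before* QC, so each reduced cohort passes through
  the same filters a fresh study would.

Each sweep row compares one degraded scan to the *single* undegraded
full-cohort baseline scan. The noise regression uses the per-condition
empirical MAE as predictor (not the nominal $\sigma$) — the realised error
is what a practitioner can estimate on real data. The cohort regression
uses percent retained, so its slope is "per 1% of cohort". Baseline rows
(σ = 0, 100%) are included in both fits by default (`include_baseline =
FALSE` excludes them). The equivalence ratio divides the MAE slope
magnitude by the cohort slope; it is reported per metric and is `NA` when
the cohort slope is numerically zero.

`fit_equivalence()` returns a classed model object with `print()`,
`summary()`, `coef()` and `predict()` methods, the package's one "fitted
model" in the classic R sense; the sweeps that feed it are deterministic
pipeline stages.

## Numerical and design choices

* All seeded functions evaluate under a temporary RNG state and restore
  the caller's stream; per-condition seeds are derived deterministically
  from the base seed and stay below $2^{31}$.
* Rounding ties anywhere in the package go half away from zero.
* MAF is the folded mean dosage over non-missing calls; per-variant
  statistics are computed in column chunks so no temporary the size of
  the dosage matrix is allocated (a 5,000 × 20,000 panel stays under
  ~0.5 GB).
* A sweep condition that fails (e.g. a degenerate phenotype) is logged
  and emitted as an `NA` row; it aborts the row, not the sweep.
* ICC is fixed to the two-way random-effects, absolute-agreement,
  single-measure form ICC(A,1), the standard choice for method-agreement
  studies with two measurement methods.

## Problem sizes used by the test suite

The property suite runs the full sweep design — 10 noise levels plus 6
cohort levels against a shared baseline — on a 5,000-sample × 20,000-variant
cohort with 5 planted loci at heritability 0.055, sized so every planted
locus is genome-wide significant at baseline while the noise grid spans
full power down to zero. The replicated monotonicity check uses a
1,500 × 4,000 cohort at heritability 0.2 with 5 replicate degradations per
level. The acceptance script uses 4,000 × 8,000 at heritability 0.07.
These sizes give stable metric trajectories on a single desktop core;
anyone reproducing the study at biobank scale only needs to raise
`n_samples`/`n_variants` and lower the heritability toward realistic
per-locus effects.

## Known limitations

* Single-engine linear scans: no mixed models, relatedness correction, or
  multi-phenotype scans; the cohort is assumed unrelated and ancestrally
  homogeneous (as after standard biobank pre-filtering, which is accepted
  as input rather than computed).
* LD-unaware locus matching: with real, long-range LD a merge distance of
  1 Mb may split or join loci differently than conditional analysis would.
* The equivalence model is linear by construction; it describes the swept
  range and should not be extrapolated to error or cohort levels outside
  it.
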