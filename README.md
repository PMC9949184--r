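# phenopower

How much GWAS power does imprecise phenotyping cost, measured in samples?

Automated phenotype pipelines (for example left-ventricular ejection
fraction, LVEF in %, extracted from cardiac MRI without manual quality
control) carry measurement error, and error in a quantitative trait
attenuates every per-variant association statistic. **phenopower** is an R
package for geneticists and methodologists who want to put a number on that
cost: it simulates a genotype–phenotype cohort with a known additive
architecture, degrades the phenotype in controlled ways, re-runs the same
covariate-adjusted association scan on every version, and expresses the
power loss from a 1% increase in phenotype mean absolute error (MAE) as an
equivalent cohort-size reduction.

## What it computes

For each variant $j$, the scan fits by OLS

$$y_i = \beta_0 + \beta_a\,\mathrm{age}_i + \beta_s\,\mathrm{sex}_i + \beta_j g_{ij} + \varepsilon_i,$$

after standard QC (sample call rate ≥ 0.98; MAF ≥ 0.01; call rate ≥ 0.95
for genotyped / INFO ≥ 0.3 for imputed variants; exact Hardy–Weinberg
p ≥ 10⁻²⁰), and calls variants with $p < 5\times10^{-8}$ genome-wide
significant. Significant SNPs are clustered into loci by single-linkage
distance clumping (1 Mb cutoff by default). A degraded scan is scored
against the undegraded baseline scan by

- **SNP accuracy** = TP / (TP + FP + FN), the Jaccard index of the two
  significant-SNP sets;
- **loci sensitivity** = peaks_correct / peaks_base, the fraction of
  baseline loci that persist (interval overlap with half-window slack).

Sweeping Gaussian noise SD 1–10 and cohort retention 100%–40%, then
regressing each metric on empirical MAE and on percent retained, yields the
**equivalence ratio**: the cohort decrease (in %) with the same effect as a
1% MAE increase.

## Worked example

```r
library(phenopower)

geno <- simulate_genotypes(n_samples = 1200, n_variants = 1500,
                           maf_range = c(0.1, 0.5), ld_block_size = 10,
                           ld_rho = 0.8, missing_rate = 0.002, seed = 301)
sim  <- simulate_phenotype(geno, causal_spec(n_causal_loci = 3,
                                             heritability_target = 0.12),
                           seed = 302)

noise_tab  <- noise_sweep(geno, sim$phenotypes, sigmas = c(1, 3, 5, 8), seed = 303)
cohort_tab <- cohort_sweep(geno, sim$phenotypes,
                           fractions = c(1, 0.8, 0.6, 0.4), seed = 304)
noise_tab[, c("condition", "mae", "peaks_base", "peaks_correct",
              "snp_accuracy", "loci_sensitivity")]
#>   condition       mae peaks_base peaks_correct snp_accuracy loci_sensitivity
#> 1         0 0.0000000          3             3    1.0000000        1.0000000
#> 2         1 0.7899908          3             3    1.0000000        1.0000000
#> 3         3 2.3918520          3             2    0.5714286        0.6666667
#> 4         5 4.0681627          3             1    0.1428571        0.3333333
#> 5         8 6.3549617          3             0    0.0000000        0.0000000

fit_equivalence(noise_tab, cohort_tab)
#> Phenotype-precision / cohort-size equivalence model
#>   loci_sensitivity: -0.1684 per 1% MAE (p = 0.00073); +0.01 per 1% cohort retained (p = 0.051)
#>     -> a 1% MAE increase is equivalent to a 16.8% cohort decrease
#>   snp_accuracy: -0.177 per 1% MAE (p = 0.0061); +0.01357 per 1% cohort retained (p = 0.019)
#>     -> a 1% MAE increase is equivalent to a 13% cohort decrease
```

Reading the output: each sweep row is one degraded scan compared against the
baseline scan — at noise SD 5 (empirical MAE ≈ 4.1%) only one of the three
planted loci is still genome-wide significant. The fitted model translates
the two sweeps into a common currency: here a 1% MAE increase costs about
as much loci sensitivity as dropping ~17% of this small cohort. (Exact
numbers are specific to this synthetic architecture and scale; the fitted
slopes steepen as cohorts shrink.)

The same stages are scriptable from a shell via
`Rscript inst/cli/phenopower.R <simulate|qc|assoc|loci|metrics|sweep-noise|sweep-cohort|equivalence|report> [options]`,
with genotypes as VCF (DS or GT), phenotypes as TSV, summary statistics as
TSV and loci as BED.

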