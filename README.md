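# lipidgen

Do GWAS-identified lipid variants, discovered largely in European-descent
samples, carry over to other populations?  `lipidgen` implements the
analysis chain used to answer that question for HDL-C, LDL-C, and natural-log
triglycerides across European American (EA), African American (AA), American
Indian (AI), and Mexican American/Hispanic (MAH) samples, for
genetic-epidemiology analysts working from summary statistics and for anyone
validating such a pipeline against simulated cohorts.

## What it computes

* **Per-stratum association**: OLS of trait on coded-allele dose *g* ∈
  {0,1,2} (additive model), under four covariate sets (unadjusted; age+sex;
  full covariates, sex-stratified; + prior MI), with t-based p-values.
* **Fixed-effects inverse-variance meta-analysis**: weights w·i = 1/se·i²,
  β̂ = Σwβ/Σw, se = (Σw)^−1/2, Cochran's Q = Σw(β−β̂)², I² = max(0,
  (Q−(k−1))/Q)·100%.
* **Replication and generalization calls**: replication = pooled p < 0.05 in
  EA (strict, uncorrected); generalization = replication **and** p < 0.05
  with EA-concordant effect direction in *every* non-EA population with
  genotype data.
* **Power accounting**: analytic power for the additive model (v =
  2f(1−f)β², λ = nv/(σ²−v)), expected significant count E = Σ power, and a
  one-sample exact binomial test of observed vs E/m (exact Poisson-binomial
  tail available).
* **Population structure**: Pearson concordance of coded-allele frequencies,
  two-population Weir–Cockerham F_ST (size-weighted and equal-weight), and
  two-locus LD (D, r², D′).
* **A seeded cohort simulator**: HWE genotypes, causal/tag SNP pairs at a
  target LD r², covariates, medication with a subtractive treatment effect,
  fasting behaviour, and additive traits with the marginal SD you ask for —
  so the whole chain is testable without restricted individual-level data.

Published summary tables for 49 lipid SNPs (60 SNP–trait associations, four
populations, with printed generalization labels) ship in `inst/extdata/` and
back the reproduction checks.

## Worked example

Simulate an African-American-like stratum where the CETP locus raises HDL-C
by 2.8 mg/dl per allele, apply the analysis exclusions, and fit the
age+sex-adjusted model:

```r
library(lipidgen)
sc <- cohort_scenario(population = "AA", study = "S1", n = 2000,
                      snp_freqs = c(rs3764261 = 0.32),
                      snp_effects = data.frame(snp = "rs3764261",
                                               trait = "HDL", beta = 2.8))
d   <- simulate_cohort(sc, seed = 7)
f   <- apply_exclusions(d, "HDL")          # adults, fasting >= 8 h
fit <- fit_additive_model(f$data, "rs3764261", "HDL", model = 2)
fit[, c("snp", "population", "n", "caf", "beta", "se", "p")]
#>         snp population    n  caf beta    se        p
#> 1 rs3764261         AA 1785 0.32 2.56 0.552 3.83e-06
```

1,785 of 2,000 simulated participants survive the exclusions; the fitted
per-allele effect 2.56 (SE 0.55) mg/dl covers the generative 2.8, and the
association is detected at p ≈ 4×10⁻⁶ — consistent with the analytic power
for this design, `analytic_power(2.8, 0.32, 1800, 15)` ≈ 0.9995.

Reproducing the published accounting from the bundled tables:

```r
print(reproduce_published())
#> Replication in European Americans (p < 0.05 ):
#>   HDL: 23/27
#>   LDL: 18/19
#>   lnTG: 14/14
#>   total: 55/60
#> Generalized SNPs per trait: HDL=5, LDL=6, lnTG=6
#> Generalized: 17 SNP-trait pairs, 16 unique SNPs
#> Mismatches against printed generalization labels: 0
#> CAF correlation vs EA:
#>   AA: r = 0.80 (49 SNPs)
#>   AI: r = 0.92 (36 SNPs)
#>   MAH: r = 0.97 (49 SNPs)
```

55 of 60 EA associations replicate; 17 SNP–trait associations (16 unique
SNPs) generalize across all genotyped populations; every one of the 60
printed Y/N generalization labels is re-derived exactly.

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end and write
tables under `results/`:

1. `01_simulate_cohorts.R` — multi-population, multi-study synthetic cohort
2. `02_association_meta.R` — exclusions, per-stratum fits, per-population IVW pooling
3. `03_generalization.R` — replication/generalization calls, simulated and published
4. `04_power_calibration.R` — expected-vs-observed significance accounting
5. `05_population_structure.R` — CAF concordance, F_ST panel, tagSNP LD demo

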