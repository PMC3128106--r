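---
title: "Methods: testing replication and generalization of lipid SNP associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing replication and generalization of lipid SNP associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgen)
```

## The scientific question

Most lipid-trait GWAS discovery has happened in European-descent samples.
Whether a reported SNP association is portable — whether it *generalizes* —
to African American, American Indian, or Mexican American/Hispanic
populations is an empirical question with two failure modes: genuine absence
of the effect (or lack of power to see it), and breakdown of the linkage
disequilibrium (LD) through which a genotyped tagSNP proxies an ungenotyped
functional variant. `lipidgen` implements the full analysis chain used to
ask that question for HDL-C, LDL-C, and natural-log triglycerides (lnTG),
plus a seeded simulator so every stage can be validated end to end without
individual-level human data (which carry access restrictions and are not
redistributable).

## Phenotype harmonisation

LDL-C is computed by the Friedewald relation
$\mathrm{LDL} = \mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/5$ (mg/dl), set
missing when TG exceeds 400 mg/dl, where the relation is unreliable.  TG is
analysed as $\ln(\mathrm{TG})$.  Before association testing we exclude
participants younger than 18 years, participants fasting fewer than 8 hours,
and (for the lnTG analysis only) participants with TG above 1,000 mg/dl.
All boundaries are read strictly: age exactly 18, fasting exactly 8 h, and
TG exactly 1,000 are retained, because the exclusion rules are stated as
strict inequalities.  When a participant trips several rules they are
charged to the first in the fixed order age → fasting → TG → medication, so
per-reason counts partition the exclusions; the ordering of multi-reason
exclusions is a reporting convention only and does not affect who is
analysed.

Participants on lipid-lowering medication are *kept* in the primary
analysis.  Two alternatives are provided: excluding them
(`apply_exclusions(..., include_medicated = FALSE)`), and restoring treated
values to the pre-treatment scale by subtracting an average per-trait
treatment effect (`adjust_for_medication()`).  Average treatment effects are
user-supplied — published drug-class averages are not reproduced here — with
package defaults of 0 (HDL-C), −35 mg/dl (LDL-C), and −0.20 ln units (lnTG)
in the simulator, magnitudes typical of statin-era lipid lowering.

## Association and meta-analysis

Each stratum (study site within population) is analysed by ordinary least
squares of the trait on coded-allele count (0/1/2), the additive model, under
four adjustment sets: (1) unadjusted; (2) age and sex; (3) age, BMI, current
smoking, type-2 diabetes, post-menopausal status and hormone use; (4) model 3
plus previous myocardial infarction.  Menopause and hormone use exist only
for women, so models 3–4 are fitted within sex strata.  Per-stratum p-values
use the t reference with residual degrees of freedom, since strata can be
small; the meta-analysis layer uses the normal reference, the standard
convention of summary-statistic pooling tools.  Missing covariates lead to
complete-case analysis.  Monomorphic SNPs are flagged inestimable rather than
fitted; rank-deficient designs raise an error naming the collinear columns.

Strata are pooled per population by fixed-effects inverse-variance
weighting: $w_i = 1/\mathrm{se}_i^2$,
$\hat\beta = \sum w_i \beta_i / \sum w_i$,
$\mathrm{se} = (\sum w_i)^{-1/2}$, heterogeneity by Cochran's
$Q = \sum w_i(\beta_i - \hat\beta)^2$ ($\chi^2_{k-1}$) and
$I^2 = \max\{0, (Q-(k-1))/Q\} \cdot 100\%$.  All strata — whole-study and
sex strata alike — are pooled flat; heterogeneity is reported, never acted
on (no random-effects fallback), matching the fixed-effects design of the
original analysis.  Mixed coded alleles across strata are a hard error: the
package never flips alleles silently.

## Replication and generalization calls

Replication (reference population, European Americans): pooled $p < 0.05$,
strict, uncorrected for multiple testing.  Generalization: replication in the
reference *and*, in every non-reference population with genotype data
("if genotyped"), $p < 0.05$ with the same effect direction as the
reference.  A zero effect fails the direction match; a SNP with no
non-reference data cannot generalize.  Ties at $\alpha$ fail.  Populations
with $\alpha \le p < 2\alpha$ are flagged as near misses, reported but never
counted.  Because one SNP can generalize for two traits, the summary reports
both tallies: generalized SNP–trait associations and unique generalized SNPs
(17 and 16 on the bundled tables — both are correct answers to slightly
different questions, so neither is privileged).

Running the classifier over the bundled summary tables reproduces all 60
printed Y/N labels, the 55/60 reference-population replication count, and
the per-trait generalized counts 5 (HDL-C), 6 (LDL-C), 6 (lnTG); this is
asserted by the test suite.

## Power calibration

Expected significant counts use analytic power for the additive model:
variance explained $v = 2f(1-f)\beta^2$, non-centrality
$\lambda = n v / (\sigma_Y^2 - v)$, and two-sided power
$1 - \Phi(z_{1-\alpha/2} - \sqrt\lambda) + \Phi(-z_{1-\alpha/2} -
\sqrt\lambda)$.  We parameterise by the *marginal* trait SD — what
population tables report — and subtract $v$ to get the residual variance;
passing `residual = "total"` uses $\sigma_Y^2$ unchanged (the difference is
negligible whenever $v \ll \sigma_Y^2$, as for all loci here).  The expected
count for a panel is the sum of powers, and the observed count is tested by
a one-sample exact binomial test with $p_0 = E/m$, two-sided via the
point-probability method.  The published table is method-ambiguous about
sidedness (one row fits a one-sided tail, another clearly two-sided), so the
method is always recorded in output and both tails are available.  An exact
Poisson-binomial tail (dynamic-programming convolution, panels up to 40
tests) is provided as the reference distribution that the binomial test
approximates; with homogeneous powers the two agree closely, which is why
the single-$p_0$ binomial is an acceptable summary.

The published expected counts themselves (17.3 etc.) depend on
per-population trait SDs that were never printed, so they are not
recomputable from public numbers; the package instead verifies the
machinery (size at $\beta = 0$ equals $\alpha$ exactly; Monte-Carlo
rejection rates of the full simulate → fit chain match analytic power within
Monte-Carlo error) and recomputes the binomial p-values from the printed
(tests, observed, expected) triples, which round to every printed value.

## Population-structure descriptives

Allele-frequency concordance is the Pearson correlation of coded-allele
frequencies between the reference population and each other population over
pairwise-complete SNPs, always reported with the SNP count used.  SNPs
appearing in more than one trait table contribute their mean frequency after
asserting within-population agreement to 0.01 (the bundled tables disagree by
at most one unit in the second decimal, e.g. 0.80 vs 0.79).  Two tables print
different coded-allele letters for two SNPs while their frequencies agree in
every population; the panel merges on frequency agreement and ignores the
letter across tables, while within any one meta-analysis mixed alleles remain
an error.

F_ST uses the Weir–Cockerham two-population variance-components estimator.
Only allele frequencies are available, so heterozygosity enters at its
Hardy–Weinberg value $2p(1-p)$, and the per-trait maximum analysed sample
sizes serve as default $n$.  Both the sample-size-weighted estimator and an
equal-weight variant are implemented and labelled: the weighted form
reproduces the published EA–AA value of 0.15 for the strongly differentiated
*FADS1* locus, while the published EA–AI value of 0.34 matches only the
equal-weight form (the original weighting convention is not documented, so
both are exposed and the report states which is used).  Estimates are not
truncated at zero; a doubly monomorphic SNP is flagged undefined.

Two-locus LD is summarised by $D = f_{AB} - p_A p_B$,
$r^2 = D^2/(p_A q_A p_B q_B)$, and $D'$, from haplotype counts.

## The simulator

`simulate_cohort()` generates what the analysis consumes: HWE genotypes at
population-specific coded-allele frequencies (binomial(2, f) draws), optional
causal/tag SNP pairs drawn from a two-locus haplotype table with $D$ set to
hit a target $r^2$ (clipped to the feasibility bounds
$\max(-p_Ap_B, -q_Aq_B) \le D \le \min(p_Aq_B, q_Ap_B)$, with a warning and
the realized $r^2$ reported when the target is infeasible), covariates,
fasting hours, medication use, and traits built additively with Gaussian
noise scaled so the marginal SD matches the scenario SD.  TG is simulated on
the ln scale and exponentiated, matching the analysis transform; total
cholesterol is constructed as LDL + HDL + TG/5 so Friedewald recovers the
intended LDL-C exactly (when TG ≤ 400); medication subtracts a constant
per-trait offset.  Trait values are floored at 1 mg/dl to keep lipids
positive; with realistic means/SDs the floor is essentially never reached.

All randomness flows from one integer seed through named streams (one per
scenario and variable class), so adding a covariate effect cannot perturb
the genotype draw, and identical seed + scenario yields a byte-identical
table.  Covariates are independent of genotypes and traits by default; a
confounding hook (`covariate_effects`) adds covariate-on-trait effects for
sensitivity analyses.  Default covariate prevalences (55% female, age
50 ± 12, BMI 28 ± 5, 25% smoking, 10% diabetes, 5% prior MI, 5–10%
medication use, 10% non-fasting) are typical of the adult population-based
cohorts this design emulates.

What the simulator deliberately omits — and hence what passing tests do not
establish about real data: family/pedigree structure and kinship (one cohort
in the original consortium was family-based), admixture and ancestry-related
confounding, survey weights, assay error, and genome-scale LD (only the
candidate SNP panel with explicit pairwise LD is generated).  Simulated
individuals are unrelated by construction.

## Numerical and testing choices

Degenerate inputs are handled explicitly: monomorphic SNPs flagged, empty
pools an error, $k = 1$ meta-analyses return $Q = 0$, $I^2 = 0$, undefined
heterogeneity p; binomial tests with $E = 0$ return exact 0/1 p-values;
p-values parsed from text that underflow double precision become the
smallest representable positive number and are flagged.  Printed p-values
are stored as text and parsed on demand so the shipped tables preserve
printed precision.

Problem sizes in the validation suite were chosen to keep the full run at a
few minutes while leaving Monte-Carlo error well below the tolerances
checked: 2,000 replicates per point on a six-point power grid (binomial
3 SE ≈ 0.03), 1,000 null replicates for the chain-level type-I error
(99% band 0.037–0.064), 500 replicates for 95% CI coverage (band 93–97%),
n = 50,000 for HWE calibration, and n = 100,000 haplotypes for LD
calibration.  The tagSNP-transferability demonstration (strong LD in the
discovery population, none elsewhere) is qualitative and seeded.

## Known limitations

* Published expected significant counts and the EA–AA frequency correlation
  rest on unpublished supplementary inputs and are not exactly recoverable
  from the shipped tables; the package recomputes what is recomputable and
  validates the machinery for the rest.
* No mixed models or kinship adjustment; no genomic control; no multiple-
  testing correction (the generalization definition is explicitly
  uncorrected).
* Units are fixed at mg/dl (no mmol/l layer); only biallelic SNPs are
  handled; haplotype phase is taken from the simulator, never inferred.
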