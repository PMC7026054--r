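---
title: "LD-adjusted eQTL scores and white-matter phenotypes: methods"
author: "eqtlwm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-adjusted eQTL scores and white-matter phenotypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlwm)
```

## The scientific problem

Expression quantitative trait loci (eQTL) are variants associated with a
gene's expression level. Given eQTL summary statistics from a discovery
study, a per-individual *eQTL score* — a weighted sum of genotype dosages
— acts as a genetic proxy for that gene's expression, computable in any
genotyped cohort without measuring expression. This package builds such
scores and tests them against diffusion-MRI white-matter phenotypes:
fractional anisotropy (FA) and mean diffusivity (MD) per tract, where
lower FA and higher MD indicate reduced microstructural integrity.

## The score model

For individual $i$ and gene (trait) $t$, with dosage vector $g_i$ coded
as 0/1/2 copies of the cohort's reference allele and discovery effect
sizes $\beta_t$ at the selected SNPs,

$$\mathrm{score}(i,t) = g_i R^{-} \beta_t,$$

where $R$ is the SNP–SNP Pearson correlation matrix estimated from a
reference panel over that gene's SNPs and $R^{-}$ its Moore–Penrose
generalized inverse. Pre-multiplying by $R^{-}$ decorrelates the
marginal effect estimates: for independent SNPs ($R = I$) the score is
the plain weighted allele count, while perfectly collinear SNPs share
one effective weight instead of being double-counted (two SNPs in
complete LD with equal $\beta = b$ each receive weight $b/2$).

The pipeline around the formula:

1. **SNP selection.** Records with discovery $p \le 10^{-5}$ are kept
   (read as the largest admissible p-value); genes with no surviving
   SNP drop out.
2. **Allele harmonization.** Effect sizes are aligned to the cohort's
   counted allele; records reported on the other allele have $\beta$
   sign-flipped. Strand-ambiguous SNPs (A/T, C/G) are dropped — with
   no strand information, flipping cannot be distinguished from
   strand mismatch — as are SNPs absent from the cohort and
   irreconcilable allele pairs.
3. **Per-gene LD blocks.** $R$ is estimated per gene over only that
   gene's selected SNPs, which keeps the dimensions of $R^{-}$ and
   $\beta_t$ equal; no genome-wide or windowed LD is computed.
4. **Cross-study de-duplication.** When two discovery studies score
   the same gene, only the score whose best SNP p-value is smaller is
   retained (exact ties go to the first-listed study, for
   determinism), so each gene enters the association stage once.
   The retained count obeys
   $\mathrm{retained} = N_A + N_B - \mathrm{overlap}$, which the run
   manifest checks on every run.
5. **Standardization.** Score columns are z-standardized across
   subjects before association, so effects are per SD of the genetic
   proxy.

## Phenotype derivation and QC

Tract measures come from a fixed 15-tract atlas (12 bilateral, 3
unilateral midline structures) contributing 27 variables: 12
association-fibre, 6 thalamic-radiation and 9 projection-fibre
variables. We treat hemisphere-level measurements as the PCA variables
— a bilateral tract contributes its left and right measures separately
— because that is the only reading under which the global PCA has
exactly 27 inputs and the categories 12/6/9; collapsing to left–right
means would leave only 15 variables.

Latent phenotypes are the first unrotated principal component over a
variable set, computed on the correlation scale (columns centered and
unit-scaled, since FA and MD variances are heterogeneous across
tracts). The component sign is fixed by requiring a positive mean
loading, so effect directions are reproducible run to run; scores are
z-standardized before association.

Subject exclusions are (i) a relatedness/cohort-overlap flag supplied
with the covariates, and (ii) a **single-pass** ±3 SD filter on the
global latent, applied separately for FA and MD (so the two analysis
samples may differ). The filter is deliberately not iterated: the mean
and SD are computed once on the full sample. The choice to apply it to
the derived global latent (rather than a pre-existing global summary
measure) is an assumption of this pipeline.

## Association models

All models adjust for age, age², sex, fifteen genetic principal
components, three scanner head-position coordinates, scanner site and
genotype array (site and array treatment-coded with the first level as
reference).

* **Unilateral tracts, global and category latents** — ordinary least
  squares of the standardized phenotype on the standardized score plus
  covariates. Reported: the score coefficient, SE, t, two-sided p, and
  incremental $R^2$ (full minus covariates-only, in percent, floored
  at 0 against floating-point underruns).
* **Bilateral tracts** — a linear mixed model on the two-rows-per-
  subject table with a subject random intercept and hemisphere as a
  within-subject fixed effect, fit by REML (`nlme`, tolerance
  $10^{-8}$, up to 200 iterations; if the default optimizer reports
  false convergence the fit is retried with the derivative-free
  optimizer, and a fit that still fails is flagged and excluded from
  FDR with a warning). With one observation per hemisphere, a random
  intercept is the richest identifiable structure. Incremental $R^2$
  for these rows is computed at the subject level, matching the
  linear path's definition.

  *Degenerate boundary.* When left and right values coincide for every
  subject, the within-subject residual variance is zero and iterative
  REML is numerically unstable (we measured fixed-effect drift of
  order $10^{-2}$ near the boundary). The analytic $\sigma^2 \to 0$
  limit of the random-intercept GLS estimator is OLS on the subject
  means, so the fitter detects the boundary (variance of left–right
  differences below $10^{-12}$ of the total variance) and uses that
  closed form, standardized on the collapsed data.
* **Quadratic models** — the standardized score and its centered
  square enter together; reported is the variance explained by the
  quadratic term beyond the linear model, in percent.
* **Cross-study comparison** — for genes scored by both discovery
  studies, both scores can be fit against the same phenotype side by
  side, bypassing de-duplication.

**Multiple testing.** Benjamini–Hochberg FDR (R's `p.adjust`,
`method = "fdr"`) is applied separately within two families per
measure: scores × individual tracts, and scores × (global + 3 category
latents). Significance is declared at $q < 0.05$. At full scale the
latent family size is `family_size(6457, 4) = 25828` tests.

## The synthetic-data generator

Real genotypes and imaging phenotypes cannot ship with a package, so
every input is simulated with known ground truth; the generator is
first-class, tested code.

* **Genotypes.** SNPs live in independent blocks; within a block, each
  haplotype's latent Gaussian has exchangeable correlation $\rho$
  (default 0.5) and is thresholded at the SNP's MAF quantile (MAF
  uniform on [0.05, 0.5]); two haplotypes are summed and the dosage
  counts reference-allele copies. This preserves block LD at
  $O(n\,m)$ cost. Reference panel and cohort share the SNP map and
  MAFs but are independent samples.
* **eQTL studies.** Each gene receives 1–15 contiguous SNPs inside one
  block (the observed per-score SNP-count range; the distribution is
  uniform, exposed as a parameter because only the range is known) and
  true standardized effects sized to explain 1–5% of expression
  variance per SNP. Each study draws its own expression realization
  (shared genetics, independent noise) and reports marginal
  per-SNP regressions, so overlapping genes get independently
  estimated statistics. About half of all records are emitted on the
  alternate allele, exercising harmonization.
* **Cohort covariates.** Age uniform on 45.92–80.67 years, sex ~48%
  male, 15 iid standard-normal genetic-PC stand-ins, two scanner sites
  at 0.843/0.157, two arrays at 0.9/0.1, three standard-normal
  head-position coordinates, and a relatedness flag on an expected 2%
  of subjects.
* **Phenotypes.** Each tract variable is a sum of a per-measure global
  factor, a category factor, a tract-specific subject component, small
  fixed covariate effects (so adjustment is exercised), the planted
  effect, and hemisphere noise, with weights solved so each variable
  has unit variance and bilateral left–right correlation equals
  `hemi_corr` (default 0.7; at 1 the hemispheres are identical, the
  mixed model's degenerate boundary). The planted effect is
  `effect_size` (default 0.05, the magnitude the pipeline is designed
  to detect) times the gene's z-standardized true expression score,
  negative on FA and positive on MD, mirroring the dominant sign
  pattern of reduced-integrity associations. Values are mapped
  affinely onto FA-like (~0.5) and diffusivity-like (~0.8) scales;
  affine maps leave standardized effects untouched.

What the generator does *not* emulate: realistic human LD maps and
allele frequencies, imputation uncertainty, genuine population
stratification (the PC stand-ins are noise), scanner artifacts, and
spatially structured tract correlations. Passing tests therefore
demonstrate correctness of the computation and calibration under the
generative model, not robustness to those real-data complications.

## Numerical choices

* Generalized inverse via SVD with relative singular-value cutoff
  $10^{-8}$ (no cutoff is prescribed for the score formula; a
  conservative SVD cutoff is the standard reading of "generalized
  inverse" and handles collinear SNPs).
* Dosage missingness is not supported: the generator produces complete
  data, and an explicit error is raised if missing values appear.
* SNPs within a gene are ordered by chromosome, position, then id, so
  weights are deterministic; scores are invariant to input record
  order.
* Zero-variance SNPs, constant covariates and constant scores abort
  with the offending column named rather than propagating NaNs.
* De-duplication ties broken by study priority, then gene id.

## Problem sizes used in the shipped tests

The test suite exercises the pipeline at desk scale, chosen to keep
the full suite in the minutes range while leaving Monte-Carlo error
well inside the asserted tolerances: null calibration at 2,000
subjects with ~200 independent scores and 5 phenotypes over 20
phenotype replicates; planted-effect recovery (0.05) at 5,000 subjects
over 100 replicates for both model paths; ranking of planted pairs in
10 end-to-end runs; oracle equivalences (brute-force score sums,
pseudoinverse identities, step-up FDR) on hundreds of random
instances.

## Known limitations

* The mixed model supports exactly two hemispheres per subject;
  incomplete subjects are dropped, not imputed.
* Family sizes follow from the supplied scores and atlas; no attempt
  is made to reproduce any particular published family size beyond the
  latent-family arithmetic.
* Scores are cis-style single-tissue proxies; no multi-tissue
  weighting or TWAS-style summary-only test statistics.
* The ±3 SD filter assumes an approximately symmetric global latent;
  with heavy skew a quantile rule would behave differently.
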