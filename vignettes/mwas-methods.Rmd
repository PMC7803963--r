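---
title: "Methods: metabolome-wide association from genetic prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome-wide association from genetic prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwaskit)
```

## The problem and the model

Metabolomes of scarce sample types (cerebrospinal fluid in particular) are
measured on cohorts of a few hundred people, far too few to test
metabolite–disease associations directly. The MWAS strategy borrows the
TWAS template: on a reference cohort with both genotypes and metabolite
levels, learn per-metabolite SNP weight vectors $w$; then, for any
phenotype with GWAS summary statistics, test the *genetically regulated*
component of the metabolite against the phenotype without ever measuring
the metabolite in the phenotype cohort.

The chain of estimands is:

1. **mQTL GWAS.** For each metabolite, OLS of the log10 abundance on each
   SNP dosage with covariates (age at draw, sex, genotyping batch, five
   genotype PCs): $y = \beta_0 + \beta g + C\gamma + e$. Betas are
   per-effect-allele; p-values use the exact t reference with
   $n - p_{design}$ df because per-cohort n is only ~150.
2. **Meta-analysis.** Fixed-effect inverse-variance weighting across
   cohorts: $\hat\beta = \sum w_i\beta_i/\sum w_i$, $w_i = 1/se_i^2$,
   $se = (\sum w_i)^{-1/2}$ — the standard-error ("STDERR") weighting
   scheme of GWAS meta-analysis, after allele harmonization.
3. **Prediction models.** LD clumping of the (fold-)GWAS
   ($r^2 < 0.1$ within 1000 kb, $p < 0.01$) yields approximately
   independent predictors; an $11\times11$ grid of elastic nets
   ($\lambda = 10^{-5},10^{-4.5},\dots,1$; $\alpha = 0,0.1,\dots,1$;
   penalty on SNPs only, covariates and intercept free) and three
   clumping-and-thresholding polygenic scores
   ($p < 10^{-4},10^{-3},10^{-2}$, raw GWAS betas as weights) compete in
   fourfold cross-validation. $\alpha=1$ is labelled LASSO, $\alpha=0$
   ridge, otherwise elastic net.
4. **Association statistic.** With harmonized phenotype z-scores $z$, model
   weights standardized by reference-panel dosage standard deviations
   ($\tilde w_j = w_j s_j$), and the panel SNP–SNP correlation matrix $R$,
   $$Z = \frac{\tilde w^\top z}{\sqrt{\tilde w^\top R\,\tilde w}},$$
   two-sided normal p. This is the standard summary-statistic test for a
   linearly imputed intermediate trait; with one SNP it reduces to that
   SNP's own z, and it is invariant to rescaling all weights.
5. **MR validation.** The clumped model SNPs act as instruments: Wald ratio
   (one instrument), IVW with multiplicative random-effects se scaling,
   MR-Egger (slope = effect, intercept = directional pleiotropy), and the
   inverse-variance weighted median with a seeded parametric bootstrap se.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `nonxeno_cut` / `xeno_cut` | 0.30 / 0.80 | inclusive missingness cuts per metabolite class |
| `sample_cut` / `post_clean_cut` | 0.40 / 0.50 | sample filter; per-cohort re-check |
| `pcs` | 5 | genotype PCs controlled in every GWAS |
| `vif_max` | 50 | variance-inflation bound on the design |
| `maf_cut` | 0.05 | post-GWAS MAF filter (inclusive removal) |
| clump | $r^2<0.1$, 1000 kb, $p<0.01$ | greedy index-SNP thinning |
| grid | 11 λ × 11 α | elastic-net search space |
| `pgs_thresholds` | 1e-4, 1e-3, 1e-2 | polygenic-score p cuts |
| `folds` | 4 | cross-validation folds, cohort-stratified |
| `model_r2_min` | 0.025 | inclusion filter: positive mean r and $r^2$ above this |
| `ridge_eps` | 0.1 | LD-matrix stabilization, shared by imputation and the Z denominator |
| `fdr` | 0.05 | per-phenotype q-value cut |

Thresholds that correct for multiple testing are computed, not configured:
genome-wide $5\times10^{-8}/338$ metabolites $= 1.48\times10^{-10}$ for a
338-metabolite discovery screen, $0.05/|{\rm discovery\ set}|$ for
replication, $0.05/(\text{models}\times\text{phenotypes})$ for the
association stage, $0.05/n_{\rm MR}$ for MR reporting.

## What the generator emulates — and what it does not

`sim_config()` defaults describe a two-cohort CSF-style study: cohorts of
155 and 136 unrelated samples, common variants (MAF ≥ 0.05, the analysis
floor), LD blocks, age ~ N(63, 7), two-thirds female, batch coinciding
with cohort. Metabolites are generated as
$10^{(\text{genetic score} + \text{covariates} + \text{noise})}$ so raw
abundances are right-skewed and log10 values Gaussian; non-xenobiotic
missingness is *left-censoring* below a detection quantile (matching the
assumption under which half-minimum imputation is justified), xenobiotic
missingness is random whole-sample absence (these cells are never imputed
and are handled complete-case). Because the reference data are too small
for heritability estimation, per-metabolite $h^2$ has no literature
anchor; the default 0.3 with one causal SNP is an engineering choice that
represents the sparse-mQTL regime the workflow is most sensitive to, and
`n_causal_snps` raises the polygenicity when wanted.

**LD construction.** Genotypes are built from two independent haplotypes
per sample; within a block each allele copies its left neighbour with
probability $\rho$ and is otherwise a fresh Bernoulli draw at the
block-constant frequency. This makes the dosage correlation *exactly*
$\rho^{d}$ at distance $d$ in expectation. A thresholded Gaussian copula
was considered and rejected: dichotomizing latent normals attenuates the
dosage correlation well below the nominal $\rho$ (measured $r^2\approx0.58$
at $\rho=0.9$), which would break the generator's contract that adjacent
$r^2 \approx \rho^2$. The price is block-constant allele frequency, which
real data do not show; none of the downstream procedures depend on
within-block frequency variation.

Not emulated: realistic human LD maps, population stratification (beyond
what distinct block frequencies induce), imputation quality, genotyping
error. Tests passing on this generator demonstrate the statistical
machinery — calibration, recovery, invariances — not performance on real
LD structure.

## Numerical and design choices

* **Predictive correlation is genetic-only.** Out-of-fold predictions use
  the SNP score alone; the unpenalized covariates help the fit but never
  count toward performance. Otherwise a metabolite with $h^2=0$ would
  "predict" through age and sex and pass the inclusion filter, defeating
  its purpose. Consequently a null metabolite's selected $cv\_r^2$
  concentrates near 0.
* **Penalized solver.** glmnet performs the coordinate descent; its
  penalty-factor rescaling (factors normalized to sum to the number of
  columns) is compensated so the requested λ applies exactly to the SNP
  block — verified against the analytic LASSO null point
  $\lambda_{max} = \max_j |g_j^\top r|/n$. $\lambda = 0$ is solved by QR
  least squares (the objective is then OLS, and exact). A single
  penalized SNP without covariates uses the closed-form univariate
  elastic net.
* **Tie-breaking in model selection** (unstated in the field's pipelines):
  highest mean out-of-fold r, then fewer mean SNPs, then larger λ —
  parsimony first. Fold-constant predictions score r = 0.
* **Ridge stabilization with unit diagonal.** Both the conditional z
  imputation and the Z denominator use $(R + \varepsilon I)/(1+\varepsilon)$
  rather than $R + \varepsilon I$: keeping the diagonal at 1 preserves the
  exact single-SNP reduction ($Z = z$) and the uncorrelated-SNP case while
  still regularizing near-singular blocks.
* **VIF guard.** $VIF_j = 1/(1-R_j^2)$ from regressing design column $j$
  on the others; a covariate-block violation excludes the metabolite, a
  SNP-only violation drops just that SNP.
* **IQR rule.** Linear-interpolation quantiles (R type 7); metabolites
  with under two observed values count as zero-IQR.
* **Replication** requires both $p$ below $0.05/|{\rm discovery}|$ and
  directional concordance; the sign requirement can be relaxed by flag.
* **Egger p-values** use the t distribution with $k-2$ df (the two-sample
  MR convention); the normal would be anti-conservative at
  $k\approx20$ instruments. Wald/IVW/weighted-median p-values are normal.
  The Wald se is first-order (outcome uncertainty only) by default, with a
  second-order option.
* **Weighted median breakdown.** The interpolated weighted median is only
  robust while valid instruments hold a strict weight majority. At the
   boundary (10 of 21 instruments pleiotropic) heterogeneous instrument
  strengths let the contaminated half capture the weight majority in a
  substantial fraction of draws, so the robustness simulation uses
  equal-strength instruments — the condition under which the estimator's
  guarantee actually applies.
* **Degenerate inputs.** Monomorphic SNPs and VIF violations yield flagged
  missing results, never exceptions; an empty clump yields a model with
  zero SNPs (r defined 0); zero-weight or unmatchable association inputs
  raise errors naming the condition.

## Reproducibility

All randomness flows from explicit seeds. The pipeline fans a single seed
out to per-stage sub-seeds (`seed + 10 × stage index`), so disabling a
stage never perturbs another stage's stream; rerunning a configuration
reproduces byte-identical outputs (hash-verified in the manifest).
Cross-validation fold assignment is a pure function of the seed and the
cohort labels, which is what makes the no-leakage property testable: after
shuffling a held-out fold's responses, that fold's trained models are
bit-identical.

## Problem sizes used in the test-suite simulations

The suite chooses compact problem sizes that keep the statistical claims
sharp: 60-SNP genomes (6 LD blocks) for replicate loops, training cohorts
of 2 × 300 for the end-to-end sign-recovery study (50 replicates, phenotype
GWAS n = 20 000), 500 replicate summary-statistic sets for the null
calibration of the association test, 200 replicates for the Egger type-I
bound, 100 for IVW coverage and weighted-median robustness, and 100 random
instances (≤ 12 SNPs) for exhaustive clumping cross-checks. These sizes
were chosen once, from power considerations, before the checks were run.

## Known limitations

* Summary-statistic imputation quality depends on how well the LD panel
  matches the GWAS population; the package reports per-SNP imputation
  $r^2$ but applies no cutoff by default.
* The MR stage inherits winner's-curse bias: instruments are the SNPs a
  predictive model selected for the same metabolite. This mirrors standard
  practice and is not corrected.
* The weighted-score test assumes the phenotype GWAS and the LD panel share
  ancestry; cross-ancestry use is out of scope.
* Storey's $\hat\pi_0$ uses a fixed $\lambda = 0.5$ rather than the
  smoother default — negligible at the list sizes involved; BH is available
  as the fully deterministic alternative.
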