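---
title: "Polygenic analysis of a cardiovascular risk score: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic analysis of a cardiovascular risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

polyfrs implements a three-arm polygenic analysis of a composite
cardiovascular risk phenotype: a per-SNP association scan, ten-fold
cross-validated p-value-binned polygenic scoring, and SNP-heritability
estimation via a genetic relationship matrix (GRM). This vignette
documents the models, the tunable parameters, the numerical choices,
and what the synthetic cohort generator does and does not emulate.

## The phenotype

The phenotype is the sex-specific risk-score linear predictor

$$
LP = \beta_1 \ln(\text{age}) + \beta_2 \ln(TC) + \beta_3 \ln(HDL)
   + \beta_{SBP}\,\ln(SBP) + \beta_{smk}\,smk + \beta_{dm}\,dm,
$$

with the treated or untreated SBP coefficient selected by treatment
status, and the published coefficient sets for men and women hard-wired
as `frs_coefficients()` defaults. Design choices worth calling out:

* **Natural logarithms** throughout: that is the convention of the risk
  functions these coefficients come from.
* **The linear predictor, not the 10-year probability, is the analysis
  phenotype.** The probability transform
  $1 - S_0^{\exp(LP - \overline{LP})}$ needs cohort-calibration
  constants ($S_0$, $\overline{LP}$) that are not part of the
  coefficient table; `compute_frs()` only computes it when those are
  supplied explicitly. Both sexes are pooled after sex-specific
  scoring, with sex available as a covariate downstream.
* **Log transform with a shift guard.** Downstream analyses use
  $\ln(LP)$ to tame outlier leverage. A linear predictor can be
  non-positive at extreme covariates, so `log_risk_score()` switches to
  $\ln(LP - \min(LP) + 1)$ when needed and records the shift in an
  attribute; either branch is strictly monotone, which is all the
  rank-based downstream reasoning requires.
* **Cohort rules.** Missing HDL is imputed with a donor-exam cohort
  mean (`impute_hdl_cohort_mean()`, flagged per subject); diabetes is
  "treated, or glucose ≥ 200 mg/dL"; subjects with any other missing
  predictor are ineligible.

## Quality control

Two regimes share one engine (`run_qc()`): the association/scoring
regime (sample & marker call rate ≥ 95%, MAF ≥ 0.01, exact-HWE p ≥
1e-4, heterozygosity outliers beyond 3 SD, subject-wise relative
pruning at PIHAT > 0.25, one-sided IBS ancestry outliers at 3 SD) and
the stricter heritability regime (call rate ≥ 99%, HWE p ≥ 0.05,
relatedness cut 0.025). Numerical/structural choices:

* **Exact HWE test.** The heterozygote count given allele counts
  follows the Levene–Haldane distribution; the p-value sums the
  probabilities of all counts no more probable than the observed one.
  Probabilities are computed on the log scale and normalized, with a
  relative tie tolerance of 1e-12.
* **Filter order and the fixed point.** Sample call rate, then marker
  filters (call rate, MAF, HWE, removals attributed to the first
  failing filter in that order), then heterozygosity, relatedness,
  ancestry. Because removing samples shifts marker statistics, the
  ordered sequence is iterated until one pass removes nothing: QC
  output is a fixed point of QC by construction.
* **Degenerate spreads flag nobody.** Z-score filters with SD = 0
  (identical samples) remove no one; heterozygosity is two-sided,
  IBS ancestry distance one-sided (only unusually *distant* samples
  are ancestry outliers).
* **PIHAT** is the plain method-of-moments IBD estimate from per-pair
  IBS counts, with allele frequencies taken from the panel itself and
  the (Z0, Z1, Z2) solution clamped to the probability simplex. Pairs
  with fewer than 50 jointly observed SNPs are undefined. There is no
  finite-sample bias correction; at the panel sizes used here the bias
  is well inside the simulation tolerances.
* **Relatedness thresholds have a noise floor.** GRM off-diagonals for
  unrelated pairs have SD ≈ $1/\sqrt{m}$. The conventional 0.025
  subject cut is meaningful at genome-wide marker counts (where it is
  >10 SD) but sits *inside* the noise at a few thousand markers; the
  analysis drivers therefore prune subjects at
  $\max(0.025,\ 4/\sqrt{m})$, while the function defaults keep 0.025.

## Association scan

Per SNP, OLS of the (log) score on A1 dosage plus covariates — age,
sex, batch dummies (first level dropped), and the top 20 genotype PCs.
Genotype missingness is handled by per-SNP casewise deletion (the
convention of the standard toolset); mean imputation is used only
inside PCA. PCs come from the eigendecomposition of the sample
covariance of standardized genotypes ($(x - 2p)/\sqrt{2p(1-p)}$),
scaled by singular values, with signs fixed so the largest-magnitude
coordinate is positive. Two-sided p-values use the t distribution with
`n_used − (#design columns + 1)` df; an optional residual-permutation
mode provides empirical p-values where the asymptotic ones are in
doubt. The genomic inflation factor is the median association
chi-square over `qchisq(0.5, 1)`.

## Cross-validated polygenic scoring

Ten folds partition the sample (sizes within one of each other); each
fold's discovery 90% gets its own association scan; SNPs land in ten
half-open p-value bins $(0,.1], \dots, (.9,1]$ (upper-inclusive, so
p = 0.1 is in the first bin and p = 1 in the last). Held-out samples
are scored per bin as the allele-frequency-weighted average
$\sum_j d_{ij}\beta_j / (2\,n_{\text{snps}})$; missing genotypes
contribute $2 p_j \beta_j$ with discovery-set frequencies by default
(a `mean_impute = FALSE` mode skips them; `average = FALSE` restores
raw sums). Held-out scores are pooled across folds and each bin gets
one phenotype-on-score regression: the pooled fit is the least-variance
reading of "one value per bin", with per-fold detail retained. The
reported adjusted $R^2$ is floored at zero, and when test-set
covariates are configured it is the *increment* of the full model over
covariates-only. Under a null phenotype the floored statistic is 0
roughly two-thirds of the time and a small positive number otherwise,
so null checks should look at medians across bins and seeds rather
than expecting every replicate to vanish.

## SNP heritability

The GRM follows the allele-frequency-weighted convention:
off-diagonals average $w_{ij}w_{kj}$ over jointly observed SNPs with
$w_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$; the diagonal uses
$1 + (x^2 - (1+2p)x + 2p^2)/(2p(1-p))$. Note two small but real
consequences of estimating $p$ from the sample: the mean off-diagonal
sits at $-\overline{\text{diag}}/(n-1)$, not 0, and a duplicated
sample's off-diagonal equals its squared standardized dosage average,
which matches the diagonal form only in expectation.

**REML.** The variance model is
$\operatorname{Var}(y) = \sigma_g^2 A + \sigma_e^2 I$. All three
iteration schemes — average information (Newton with
$\tfrac12 y'PV_iPV_jPy$), Fisher scoring (Newton with
$\tfrac12\operatorname{tr}(PV_iPV_j)$), and EM — maximize the same
restricted likelihood
$-\tfrac12[\ln|V| + \ln|X'V^{-1}X| + y'Py]$. Implementation notes:

* One eigendecomposition $A = U D U'$ makes $V$ diagonal in the
  rotated basis, so each iteration is $O(n^2)$; the decomposition can
  be shared across algorithms (`grm_eigen`).
* Newton schemes take one EM warm-up step, then use step halving
  whenever a step would leave the positive-definite cone or reduce the
  likelihood (EM needs no such guard: its iterations are monotone, and
  the test suite asserts that per iteration).
* Negative components are projected to $10^{-6}V_p$ (constrained
  fitting, the standard default; `constrain = FALSE` disables).
* Convergence is $|\Delta \log L| < 10^{-8}$ with a 200-iteration cap.
  EM approaches the optimum geometrically and is the slowest of the
  three; at this tolerance the three algorithms' $\sigma_g^2$ agree to
  a few parts in $10^5$ of $V_p$ away from the boundary. Near the
  $h^2 = 0$ boundary EM can stall a little short, which is visible as
  a slightly different (lower-likelihood) estimate.
* Standard errors come from the inverse average-information matrix at
  the optimum for *all* algorithms (so columns differ only via the
  path taken), and $se(h^2)$ by the delta method.
* A singular information matrix (e.g. $A \approx I$, where $\sigma_g^2$
  and $\sigma_e^2$ are unidentifiable) falls back to a pseudo-inverse
  Newton step; the likelihood then still converges to the OLS
  restricted likelihood even though the split between components is
  arbitrary.

**Haseman–Elston.** The phenotype is residualized on covariates and
standardized; for every pair with $A_{ij} \le 0.025$ (close-relative
*pairs* are excluded, not subjects) the cross-product $z_i z_j$ is
regressed on $A_{ij}$; the slope is the heritability estimate. The
classical squared-difference form $(z_i - z_j)^2$ is available and maps
through $-\text{slope}/2$; the cross-product form is the default for
its efficiency. Pair filtering is selection on the regressor only, so
it does not bias the slope.

**Bootstrap inference.** Pairwise observations sharing a subject are
dependent, so inference resamples subjects with replacement, forms all
pairs among draws originating from distinct subjects, and reruns the
pair regression; SE is the SD of bootstrap slopes, the CI the 2.5/97.5
percentiles, and the p-value a two-sided percentile sign test. A
caveat this package measures and documents rather than hides: under an
exact null the pairwise kernel is first-order degenerate (each
subject's conditional expectation is zero), and the with-replacement
subject bootstrap is known to be inconsistent for degenerate pairwise
statistics — its SE overshoots the true sampling SD by roughly a
factor of two at desk-scale panels, making null rejections rarer than
nominal. Under genuine genetic signal the kernel is non-degenerate and
the bootstrap behaves. Interpret H-E bootstrap p-values as
conservative.

## The synthetic cohort generator

`simulate_genotypes()` + `simulate_phenotype()` +
`simulate_covariates()` provide ground truth for every stage: biallelic
SNPs in HWE with a Uniform MAF spectrum, optional two-subpopulation
Balding–Nichols divergence (even split), duplicates sharing all
genotypes, sib pairs sharing each allele with probability 1/2 per
locus (expected relatedness 1/2, no LD), Bernoulli missingness with a
batch-"B" boost, an additive polygenic trait with effects drawn on
standardized genotypes (so the target $h^2$ is frequency-independent,
matching the GRM weighting), and a clinical covariate panel with
realistic marginals. A `genetic_sd` option injects a polygenic
component into cholesterol, HDL and SBP so the risk-score *pathway*
itself is heritable.

What it deliberately does not emulate: linkage disequilibrium (every
SNP is independent, so binning and scoring see no tag-SNP redundancy),
multi-generation pedigrees, imputation error, genotyping-intensity
artifacts, and cryptic relatedness beyond the planted pairs. Passing
tests therefore demonstrate correctness of the estimators under the
assumed sampling model, not robustness to LD or array artifacts.

```{r example}
library(polyfrs)
sim <- simulate_genotypes(sim_config(n_samples = 500, n_snps = 1000,
                                     h2_true = 0.5, seed = 1))
ph  <- simulate_phenotype(sim$panel, h2_true = 0.5, n_causal = 100,
                          seed = 2)
g   <- compute_grm(sim$panel)
reml_fit(g, ph$phenotype, algorithm = "AI")
he_regression(g, ph$phenotype)
```

## Problem sizes

The shipped test suite and acceptance script run simulation studies at
n = 500–2000 samples and m = 400–10000 markers: parameter recovery uses
20 replicates per heritability level at n = 1000, m = 2000 (the mean
$\hat h^2$ then has a standard error near 0.015, comfortably inside the
recovery bands); GWAS calibration uses 10,000 null markers; bootstrap
calibration uses 200 null cohorts of n = 120. These sizes keep each
study's Monte-Carlo error well below the bands it is checked against
while completing in minutes on one core.

## Known limitations

* No LD: effective marker counts, bin occupancies, and GRM noise all
  scale differently on real array data.
* The relatedness thresholds inherited from genome-wide practice
  assume $m$ large; below ~10⁴ markers use the noise-floor rule above.
* H-E bootstrap p-values are conservative under the null (degenerate
  kernel; see above).
* X-chromosome checks, haplotype-based missingness tests and
  LD-aware scoring are out of scope.
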