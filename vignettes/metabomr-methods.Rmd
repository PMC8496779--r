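---
title: "Methods: matched metabolome-wide risk scans and exposure MR profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched metabolome-wide risk scans and exposure MR profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

This vignette documents the models, the assumptions behind them, the
numerical choices, and what the synthetic-data generator does and does not
emulate.  It is the package's design record: every decision that was
genuinely open is stated here with its rationale.

## 1. The matched risk model

For a 1:1 matched case–control design the conditional likelihood removes
the per-set nuisance intercepts and reduces to intercept-free logistic
regression on within-pair covariate differences
$\Delta x_i = x_{\text{case},i} - x_{\text{control},i}$:

$$\ell(\beta) = \sum_i \log \sigma(\beta^\top \Delta x_i), \qquad
  \sigma(t) = (1+e^{-t})^{-1}.$$

Exposures are log-transformed, z-scored metabolite concentrations, so
$e^\beta$ is an odds ratio per 1 SD of log concentration — the scale on
which panel-wide effects are comparable.

**Optimisation.**  The log-likelihood is concave; we use Newton–Raphson
with step-halving from $\beta = 0$, declaring convergence when the maximal
score component falls below $10^{-8}$ (at most 50 iterations).  Standard
errors come from the observed information at the MLE and inference is Wald
(two-sided), matching the OR (95 % CI) reporting convention of
epidemiological tables.  Two pathologies are flagged rather than reported
as estimates: a design whose differences are all zero (score identically
zero, $\hat\beta$ undefined) and separation (the score becomes numerically
flat at a huge $\hat\beta$; we treat $|\hat\beta| > 15$ — an OR beyond
$3\times10^6$ per SD — as separation).  The optimizer is cross-checked in
the test suite against coarse-to-fine grid maximisation of the analytic
conditional log-likelihood and against an independent conditional-logistic
implementation (`survival::clogit`).

**Adjusted models.**  `bmi_adjusted` adds BMI; `fully_adjusted` adds BMI,
smoking status, pack-years (entered linearly — the categorisation is not
standardised across studies, so the simplest well-defined choice is used
and recorded), alcohol (g/day) and hypertension; `fasting_adjusted` adds
fasting status.  Adjusted fits are complete-case: pairs missing any
modelled variable are dropped, so adjusted and crude models may use
different pair counts (reported per estimate).

**Stratified analyses.**  Pairs are assigned to strata by the *case's*
covariate value: matching variables are shared within a pair, non-matching
covariates differ, and anchoring on the case is the conventional choice
when the design does not dictate one; the choice is recorded in the output.
Continuous stratifiers are cut at the pooled median.  Heterogeneity across
strata uses Cochran's Q on the stratum log-ORs,
$Q = \sum_k w_k(\beta_k - \bar\beta)^2$ with $w_k = 1/SE_k^2$, referred to
$\chi^2_{K-1}$ — the conventional test when only stratum estimates and SEs
are available.

## 2. Discovery: the effective number of tests

Metabolite panels are heavily correlated, so Bonferroni on the raw column
count is too severe.  The effective number of tests (ENT) is the smallest
number of principal components of the metabolite **correlation** matrix
whose cumulative eigenvalue fraction *exceeds* 0.95 ("more than 95 %" is
read strictly, so an exactly-equal boundary does not stop the count; the
equal-eigenvalue case is covered by a test).  The correlation (not
covariance) matrix is used because inputs are z-scored; eigenvalues are
computed on all samples pooled (cases and controls), and ENT is computed
separately per platform since panel sizes and correlation structures
differ by an order of magnitude between targeted and untargeted assays.

The pooled significance threshold is $0.05/\text{ENT}$.  A metabolite is a
**robust hit** when pooled $p \le 0.05/\text{ENT}$ *and* $p \le 0.05$ in at
least two cohorts independently; both comparisons are boundary-inclusive
("equal or below"), and cohorts without an estimate count as
non-significant.

## 3. Panel quality control

* **Limit-based imputation** — below-LLOQ values (below-LOD for
  semiquantified classes: acylcarnitines, glycerophospholipids,
  sphingolipids) are imputed at half the batch-specific limit; above-ULOQ
  values are capped at the ULOQ; cells with an out-of-range internal
  standard stay missing.  The operation is idempotent.
* **Sparsity exclusion** — a metabolite with fewer than 100 above-limit
  values in *any* cohort is dropped; "fewer than" is strict, so a count of
  exactly 100 retains.
* **Untargeted rescaling** — each feature is divided by the median of its
  observed values and missing values are filled with the post-scaling
  minimum observed value, the standard normalisation for area-count
  feature tables.
* **Derived ratios** — molar sums/ratios are appended as
  pseudo-metabolites from user-supplied definitions; the Fischer ratio
  (Leu+Ile+Val)/(Phe+Tyr) ships as the built-in default.  A zero
  denominator yields a missing value, never an infinity.
* **Log z-scoring** — natural log, then per-metabolite centring/scaling.
  The base is immaterial (absorbed by the z-score; asserted by a test).
  Scaling is per cohort by default — each cohort is standardised before
  pooling, which also absorbs cohort-level assay shifts — with a global
  mode available (`cohort = NULL`).  Zero-variance columns cannot be
  z-scored and are dropped with a warning (an all-degenerate matrix is an
  error).
* **Cross-platform merging** — ids are canonicalised (case, whitespace)
  for the set arithmetic; metabolites measured on both platforms are kept
  as distinct columns and linked by an alias map, never averaged, so each
  platform reports its own estimate.

## 4. Two-sample MR

**Instrument selection** filters exposure associations at
$p < 5\times10^{-8}$ and greedily prunes LD: SNPs are visited by ascending
p and kept only if $R^2 < 0.01$ with every SNP already kept.  Without a
user-supplied LD matrix the p-passing set is assumed pre-pruned, as
published instrument lists are; this is recorded in the provenance.

**Harmonisation** aligns outcome tables to the exposure's effect alleles:
swapped alleles flip the outcome beta and complement the EAF; strand flips
are resolved through allele complements; palindromic SNPs (A/T, C/G) with
an EAF in [0.42, 0.58] on either side are dropped as strand-ambiguous
(window configurable; outside the window they are aligned by frequency).
Every drop carries a reason.

**Estimators.**

* IVW: weighted regression through the origin,
  $\hat\beta = \sum w_j \beta_{Xj}\beta_{Yj} / \sum w_j \beta_{Xj}^2$,
  $w_j = 1/se_{Yj}^2$.  The SE is inflated by $\sqrt{Q/(J-1)}$ when
  Cochran's Q exceeds its degrees of freedom — the multiplicative
  random-effects convention of the main MR software family.  Whether
  fixed- or random-effects IVW is intended is often unstated in
  applications; the inflation rule is our explicit assumption, and it is
  conservative under the null (Q exceeds its df half the time even without
  heterogeneity, so null rejection rates run at or below the nominal
  level).
* MR–Egger: weighted regression *with* an intercept, the intercept
  estimating average directional pleiotropy.  Exposure betas are oriented
  positive first (flipping the sign of both betas), as the method
  requires; the same overdispersion inflation applies with $J-2$ df.
* Weighted median: Wald ratios $\theta_j = \beta_{Yj}/\beta_{Xj}$ ordered
  ascending with normalised delta-method weights
  $\beta_{Xj}^2/se_{Yj}^2$; the estimate interpolates the ordered ratios
  at cumulative weight 0.5 using midpoints $s_k = \sum_1^k w_j - w_k/2$.
  The SE is the SD over parametric bootstrap resamples of both beta
  vectors (default 1000; seed a config key, so the SE is reproducible
  bit-for-bit).  SNPs with $\beta_X = 0$ have no defined ratio and are
  dropped with a warning.

**Panel scan** (`mr_scan`) runs instrument selection once, then
harmonisation and all three estimators per metabolite, flagging IVW
p-values below the platform's ENT-corrected threshold — the same
thresholds as the observational scan, so the two profiles are comparable.

## 5. Instrument-specificity screen

For a candidate metabolite's instruments, the variance explained in every
panel metabolite is accumulated as $\sum_j 2f_j(1-f_j)\beta_j^2$, which
assumes a standardized trait and Hardy–Weinberg equilibrium (when EAF is
unavailable, $z^2/n$ is the documented fallback).  No numeric criterion
for "specific enough" is standard, so the package makes the judgment
reproducible instead: the candidate's rank among all metabolites, the
ratio of its cumulative $R^2$ to the best other metabolite's, and a
pleiotropic flag raised whenever the candidate is not uniquely rank 1
(ties count as pleiotropic).

## 6. Profile comparison and the negative control

Effect profiles are standardized as estimate/SE — log-OR (never OR) for
risk estimates, beta for MR estimates — and correlated by Spearman rank
correlation on the id intersection, with average ranks for ties and a
two-sided p from the t approximation (an exact permutation p is available
for $n \le 10$).  Platforms are never mixed in one correlation.  The
negative-control workflow repeats the comparison against the MR profile of
an exposure with no plausible metabolome effect and additionally counts
how many risk-robust metabolites pass the MR threshold under that null
exposure — approximately zero in a calibrated analysis.

## 7. The synthetic-data generator

The generator produces data with *exactly* the structure the estimators
assume, so parameter-recovery tests are clean.

* **Metabolome**: log concentrations follow a latent factor model
  $x = \Lambda f + \beta_{BMI}\,\mathrm{bmi} + \varepsilon$ with loadings
  drawn once per run (default scale $1/\sqrt{k}$, unit noise), then
  exponentiated; detection limits sit at a configurable quantile of each
  metabolite's per-batch marginal, and censored cells are flagged but not
  imputed — imputation is the QC stage's job.
* **Case assignment**: both pair members share the matching variables; the
  case label follows the softmax
  $P(\text{member 1 is case}) = e^{\eta_1}/(e^{\eta_1}+e^{\eta_2})$ with
  $\eta = \sum_j \beta_j z_j + \beta_{BMI} z_{BMI}$.  This makes the 1:1
  conditional likelihood exactly correct — deliberately chosen over
  population sampling + matching so that recovery tests measure estimator
  quality, not design approximation.  BMI is standard normal and acts on
  both metabolites and risk, reproducing the confounding structure that
  BMI adjustment must remove (a property test verifies: crude estimate
  biased, adjusted estimate unbiased).
* **GWAS summary statistics**: standard errors follow the standardized-
  trait approximation $1/\sqrt{2f(1-f)n}$.  True exposure effects are
  drawn positive — the effect allele is taken as the exposure-increasing
  allele — in absolute units anchored to a reference GWAS size of
  $7\times10^5$, so that (i) at the default exposure size instruments sit
  at $|z|\in[6,20]$, past genome-wide significance, and (ii) sampling
  noise vanishes as the configured sample sizes grow, recovering the
  noise-free Wald-ratio identity.  The positive orientation is what makes
  a nonzero mean pleiotropic effect *directional* (recoverable by the
  Egger intercept) rather than self-cancelling.  Outcome effects are
  $\theta\gamma_j + \alpha_j$ with
  $\alpha_j \sim N(\mu_{pleio}, \sigma_{pleio}^2)$.  A configurable
  fraction of SNPs (default 10 %) is palindromic to exercise
  harmonisation.  The negative-control generator is the same machinery
  with $\theta = 0$ against every metabolite.
* **Not emulated**: individual genotypes, LD beyond a user-suppliable
  $R^2$ matrix, mass-spectrometry drift beyond per-batch limits, cohort
  calipers (matching is exact by construction), and non-European allele
  frequency spectra.  Passing tests therefore demonstrate correctness of
  the statistical machinery under its own assumptions, not robustness to
  assay artefacts or model misspecification in real cohorts.

## 8. Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen to give
stable Monte-Carlo estimates while keeping a full run in minutes:
coverage and bias at 300–500 replicates of 1,000-pair cohorts; estimator
recovery at 100–549 instruments over 120–500 replicates; null calibration
at 1,000 conditional-logistic fits and a 200-metabolite IVW panel; the
negative-control correlation over 100 replicates of a 50-metabolite panel.
Every generator takes an explicit seed and is bit-reproducible under it;
the pipeline writes per-stage manifests recording seeds and configuration
so reruns are byte-identical.

## 9. Known limitations

* Only 1:1 matched sets: the conditional likelihood for n:m sets is out of
  scope.
* The heterogeneity test and the IVW/Egger overdispersion rule are
  conventions; other choices (likelihood-ratio heterogeneity,
  fixed-effect IVW) would give slightly different SEs.
* The ENT depends on the sample correlation matrix and therefore on n;
  with few samples and many metabolites it is bounded by the sample count.
* The specificity screen quantifies shared variance, not causal pathways;
  a multivariable-MR adjustment for correlated metabolites is deliberately
  not provided.
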