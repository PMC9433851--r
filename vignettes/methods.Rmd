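---
title: "Methods: mode-matched bootstrap contrasts of structural co-variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mode-matched bootstrap contrasts of structural co-variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccamodes)
```

## The analysis problem

Two sets of brain measurements are observed per participant: volumes of the
38 hippocampal (HC) subfields (FreeSurfer-style sub-segmentation: CA1, CA2/3,
CA4, dentate gyrus, subiculum, presubiculum, parasubiculum, HATA, fimbria,
fissure, molecular layer and tail, split into head/body and hemisphere) and
volumes of 91 default-network (DN) parcels grouped into temporal, prefrontal,
parietal and posterior-cingulate territories. The scientific questions this
package operationalizes are:

1. Which *modes of co-variation* link combinations of HC subfields to
   combinations of DN parcels across a population?
2. For a binary phenotype (here: low vs adequate social support), which
   individual subregion weights within those modes differ reliably between
   the groups?
3. Do participants' expressions of those modes relate to their polygenic
   liability for the phenotype?

## Model and procedure

### Deconfounding

Each volume column is residualized by OLS on a confound design (intercept;
age, age², sex, sex×age, sex×age²; any further numeric nuisance columns such
as head size, motion, scanner position or site proxies), then z-scored to
zero mean and unit *sample* variance (n−1 denominator; tests pin this
convention). Interaction terms are computed from uncentered age when absent —
a documented choice, since a centering convention is not dictated by the
procedure itself. Missing values are rejected rather than imputed: the
intended cohort is complete-case. Deconfounding is performed once on the full
cohort before any group split; deconfounding per group would subtract
group-specific nuisance fits and thereby leak group information into the
residuals.

### Canonical correlation decomposition

With deconfounded, z-scored views $X \in \mathbb{R}^{n\times p}$ (DN) and
$Y \in \mathbb{R}^{n\times q}$ (HC), CCA finds weight pairs $(v_l, u_l)$
maximizing $\operatorname{corr}(X v_l, Y u_l)$ subject to within-view
uncorrelatedness. `fit_cca()` computes the SVD of the whitened
cross-covariance $R_x^{-T} S_{xy} R_y^{-1}$ (Cholesky factors
$S_{xx}=R_x^TR_x$, $S_{yy}=R_y^TR_y$), which is numerically stabler than the
generalized eigenproblem. Conventions, each pinned by a test:

* modes are ordered by canonical correlation, descending; ties keep input
  order;
* canonical vectors are scaled so each variate has unit sample variance,
  making weights comparable across modes;
* per-mode sign is fixed so the largest-magnitude HC weight is positive, so
  repeated fits are byte-identical (CCA is otherwise sign-indeterminate);
* `k` defaults to 25 modes, the depth at which such decompositions are
  conventionally examined for these two variable sets; it is configurable;
* no regularization by default (intended regime $n \gg p+q$); a ridge on the
  within-view covariances is available for degenerate or small-$n$ synthetic
  runs and for rank-deficient inputs.

### Mode-matched bootstrap group contrast

Mode order and sign are not identifiable across refits, so group solutions
cannot be subtracted naively. `bootstrap_group_difference()`:

1. fits a reference CCA on the full cohort;
2. in each of $B$ (default 100) replicates, resamples each group with
   replacement to its own size (stratified; a pooled-resampling variant is
   available behind `pooled_resample` for sensitivity analysis), fits one CCA
   per group;
3. aligns each group solution to the reference by maximizing total absolute
   Pearson correlation between concatenated canonical vectors $[v_l; u_l]$
   over all mode assignments (optimal linear assignment, not greedy), with
   signs flipped where the matched correlation is negative;
4. records the elementwise difference of aligned canonical vectors (low
   support minus adequate support) per mode and subregion;
5. forms the 10th/90th percentile interval of the $B$ draws per cell and
   flags a "hit" where the interval excludes zero.

Design choices made where the procedure is genuinely open:

* **Matching target.** Both group solutions are aligned to one full-cohort
  reference rather than to each other: this fixes their mutual
  correspondence *and* a stable orientation across replicates in a single
  step, which aggregation over replicates requires.
* **Matching signature.** Matching uses the concatenation of both views'
  vectors, so a mode is identified by its full anatomical signature rather
  than one side only.
* **Assignment algorithm.** Optimal assignment (Hungarian, $O(k^3)$) instead
  of greedy matching avoids cascade errors when neighboring canonical
  correlations are close; it is verified against exhaustive search.
* **Interval.** The percentile method at 10/90 — an 80%-coverage two-sided
  interval — with no bias correction; `determine_hits()` recomputes flags at
  other coverages from the stored draws without refitting. Widening the
  interval can only turn hits off (tested).
* **Degenerate matches.** Replicates with a match score below 0.5 are kept
  but counted (`n_flagged_replicates`); with well-separated modes the
  flagged fraction is near zero.
* **Multiplicity.** No correction across the $k(p+q)$ cells, matching the
  procedure being emulated; the number of tests is echoed in the result so a
  reader can apply their own.

Under the null (no group difference) the hit rate of an 80% interval should
be near 20% per cell; the acceptance suite verifies calibration
(50 synthetic seeds, $n$=2000/group) and power against a planted loading
perturbation ($\delta$=0.5 on one HC entry of mode 1, flagged in ≥90% of
seeds).

### Polygenic scoring and Bayesian logistic association

SNP effect sizes are consumed as given (GWAS estimation, clumping and
threshold optimization are upstream concerns). `snp_qc()` excludes SNPs with
MAF < 1%, imputation info < 0.8 (strict inequalities, so info = 0.8 is
retained), duplicate ids, and palindromic A/T / C/G SNPs when alleles are
provided. `compute_prs()` forms $\mathrm{prs}=\sum_i g_i \hat\beta_i$ over
passing SNPs; `select_extremes()` labels the top and bottom 5% (stable
tie-break by (score, participant id)) and drops the middle.

`fit_bayesian_logistic()` regresses the extreme-group indicator on the 25
mode expressions with sex-specific intercepts and sex-specific slopes on
z-scored age; every coefficient has a standard normal prior:

$$\operatorname{logit} P(y_i=1) = \sum_{j=1}^{25} x_{ij}\beta_j +
\alpha_{\mathrm{sex}[i]} + \alpha^{\mathrm{age}}_{\mathrm{sex}[i]}
\tilde a_i, \qquad \beta_j, \alpha \sim \mathcal N(0,1).$$

Sampling uses JAGS's GLM block sampler with three chains and per-chain seeds
derived from one master seed. The HC-side and DN-side variate sets are fitted
as two separate runs of the same model. A coefficient is *relevant* when its
95% equal-tailed credible interval excludes zero. The one-sided posterior
mass $P(\operatorname{sign}\beta\ \text{constant})$ is also reported; note
that flagging at 95% *one-sided* mass would imply a ~10% per-coefficient
null rate, whereas the credible-interval rule implies ~5%, which is what the
calibration suite checks. Convergence is assessed per coefficient (split
R-hat ≤ 1.01, ESS ≥ 400); a failing fit is returned marked unreliable with a
warning, never silently. A linear-outcome variant (`family = "linear"`) is
available for regressing the continuous score instead of the extreme-group
label; variates are z-scored before entering the model by default
(`scale_variates`), both switchable because neither choice is dictated.

## The synthetic cohort generator

`generate_cohort()` draws, per participant, latent factors
$z_l \sim \mathcal N(0, s_l^2)$ with strictly decreasing strengths $s_l$
(defaults $3 > 2 > 1$ against unit noise), and emits
$X = \sum_l z_l a_l^T + E$, $Y = \sum_l z_l b_l^T + F$ with sparse unit-norm
loadings. This linear construction is chosen deliberately: CCA is consistent
for it, and the population canonical correlations are available in closed
form (eigenvalues of $\Sigma_{xx}^{-1}\Sigma_{xy}\Sigma_{yy}^{-1}
\Sigma_{yx}$), giving an independent oracle for the engine. Further
structure:

* **Group perturbation** is applied to *loadings* (a $\delta$ shift on named
  entries for the "isolated" group), not to volume means, because the
  contrast operates on canonical vectors, not averages.
* **Confounds** (age $\sim\mathcal N(55, 7.5^2)$ years, sex, three
  standard-normal scanner-like nuisances, plus the derived age²/sex×age
  terms) contribute linearly with known coefficients whose scale is
  `confound_strength` (0 switches contamination off for oracle tests).
* **Genotypes** are binomial dosages at uniform MAF in [0.05, 0.5] with no
  linkage structure; `prs_mode_coupling` $\rho$ mixes the standardized true
  score into a designated mode's factor,
  $z_1 \leftarrow \rho\,s_{\mathrm{std}} + \sqrt{1-\rho^2}\,\varepsilon$, so
  genetic liability and that mode's expression correlate by construction.
  The end-to-end study condition uses $\rho = 0.3$ — a weak-but-real
  coupling in line with the small effect sizes typical of polygenic
  score–brain associations.
* **Reproducibility.** One master seed drives separate sub-streams for
  loadings, genotypes, factors/noise and confounds, so e.g. changing
  `n_snps` does not alter the volume draws (unless coupling is active, which
  by construction ties the streams).

What the generator does *not* emulate: measurement units and the empirical
covariance scale of real subregion volumes (all quantities are unitless),
spatial autocorrelation between neighboring parcels, linkage disequilibrium
among SNPs, non-linear confound effects, and site/batch heterogeneity
beyond linear proxies. Passing tests therefore certify the *procedure* —
calibration, recovery, invariances — not performance on any particular real
dataset.

## Numerical choices and degenerate inputs

* Rank-deficient within-view covariance (e.g. noiseless single-factor data)
  aborts with advice to reduce `k` or add a ridge; tests exercise the ridge
  path.
* Constant columns cannot be z-scored and are rejected by name, as are
  collinear confound columns (identified via QR pivoting), mismatched
  participant-id sets, out-of-range dosages, and fully tied score vectors
  (extremes undefined).
* Quantiles use the default continuous type of `stats::quantile()`;
  `determine_hits()` applies the same definition as the fitting path, and the
  oracle tests compare against an independent computation on explicit draw
  lists.
* An all-zero hit table reports shares as `NA` ("undefined"), never 0/0.

## Problem sizes used in the validation suite

The shipped suites run at deliberately scaled sizes chosen to make the
statistical assertions sharp while staying desk-sized: CCA oracle agreement
at $n = 20\,000$; contrast calibration over 50 seeds and planted-effect power
over 20 seeds at $n = 2000$ per group with $B = 100$; genetic-stage
calibration over 20 seeds at $n = 2000$; the weak-prior MLE-limit check at
$n = 50\,000$ with shortened chains (the posterior mean is the only quantity
consumed there); and the end-to-end coupled-mode power over 10 seeds at
$n = 5000$ participants. `scripts/acceptance.R` recomputes the same families
of quantities at reduced seed counts.

## Known limitations

* The published parcel-to-category mapping for the DN is not public; the
  shipped mapping (23 temporal, 30 prefrontal, 22 parietal, 16 posterior
  cingulate parcels) is a labeled reconstruction, as is the subregion-level
  hit-location fixture, which reproduces the encoded tables' cells exactly
  but distributes hits across hemispheres/portions from the accompanying
  descriptions.
* The encoded HC hit-count table is internally inconsistent as printed (its
  PrS cells sum to 5 while its total row prints 4; its cells sum to 33 while
  its total row sums to 32). Both readings are preserved — computed margins
  from cells, printed totals verbatim — and never silently "fixed".
* Bootstrap inference is purely resampling-based; no parametric covariance
  of CCA weights is offered.
* The generator's factor model is exactly the regime in which CCA is
  consistent; real volumetric data need not follow it.
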