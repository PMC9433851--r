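# ccamodes

Population-level **modes of structural co-variation** between two brain
subregion systems — the 38 hippocampal (HC) subfields and 91 default-network
(DN) parcels — with group-difference inference on the modes' anatomical
weights and a genetic-association stage. The package is aimed at
population-neuroscience analysts who have per-participant subregion volume
tables (plus confounds, a binary phenotype, and optionally genotypes with
GWAS effect sizes) and want the full chain as tested, reusable functions.

## What it computes

1. **Deconfounding** — each volume column is residualized by OLS on a
   configurable nuisance design (age, age², sex, sex×age, sex×age², head
   size/motion/position, site proxies, …) and z-scored
   (`residualize()`, `zscore_columns()`).
2. **Canonical correlation analysis** — for views $X$ (n×p, DN) and $Y$
   (n×q, HC), `fit_cca()` finds weight pairs $(v_l,u_l)$ maximizing
   $\rho_l=\operatorname{corr}(Xv_l,\,Yu_l)$, by SVD of the whitened
   cross-covariance; modes are ordered by $\rho$, variates have unit
   variance, and signs follow a deterministic convention.
3. **Mode-matched bootstrap contrast** — `bootstrap_group_difference()`
   resamples each phenotype group B=100 times, fits one CCA per group,
   aligns both to a full-cohort reference in mode order *and* sign
   (`match_modes()`, optimal assignment on absolute correlations of
   concatenated canonical vectors), and records elementwise canonical-vector
   differences. A subregion is a **hit** for a mode when the 10/90%
   percentile interval of its difference draws excludes zero.
4. **Genetic association** — `snp_qc()` (MAF < 1%, info < 0.8, duplicates,
   palindromic SNPs), `compute_prs()` ($\mathrm{prs}=\sum_i g_i\hat\beta_i$),
   `select_extremes()` (top vs bottom 5% as a binary outcome), and
   `fit_bayesian_logistic()` — MCMC logistic regression of the extreme-group
   label on 25 mode expressions with sex-specific intercepts/age slopes and
   $\mathcal N(0,1)$ priors; coefficients whose 95% credible interval
   excludes zero are flagged.
5. **Reporting** — `tally_hits()` produces the HC (12 subfield categories)
   and DN (4 lobe categories) hit tables with margins and shares;
   `laterality_summary()` and `head_body_summary()` give hemisphere and
   head/body breakdowns.
6. **Synthetic cohorts** — `cohort_spec()` / `generate_cohort()` plant known
   latent modes, loading perturbations, confound contamination and a
   genotype-coupled mode, so every stage is testable against ground truth.
7. **Pipeline** — `run_pipeline()` ties the stages together from a YAML
   config with provenance-stamped outputs.

## Worked example

```r
library(ccamodes)

spec <- cohort_spec(n_per_group = 1000, delta = 0.5,
                    perturbed_entries = list(list(mode = 1, side = "hc", index = 5)),
                    seed = 42)
co  <- generate_cohort(spec)
dn  <- deconfound(co$dn_volumes, co$confounds)
hc  <- deconfound(co$hc_volumes, co$confounds)

sol <- fit_cca(dn, hc, k = 3)
sol
#> cca_solution: 3 modes, n = 2000, p = 91 (DN), q = 38 (HC)
#> canonical correlations: 0.902 0.804 0.511

res <- bootstrap_group_difference(dn, hc, co$group_labels,
                                  B = 100, k = 3, seed = 42)
res
#> contrast_result: B = 100 replicates, 3 modes x 129 subregions, 66 hits (387 tests, uncorrected)
#>   26 replicate(s) carried a low-quality mode match

# the perturbed HC entry (5th subfield column) in mode 1:
res$hit_flags[1, 91 + 5]
#> [1] TRUE

tabs <- tally_hits(res)
tabs$hc$grand_total
#> [1] 20
```

The canonical correlations are the planted factor strengths (3, 2, 1 against
unit noise) seen through sampling. The perturbed loading entry surfaces as a
mode-1 hit; the remaining hits reflect the ~20% per-cell rate expected of an
80%-coverage interval under no true difference. At this deliberately modest
sample size the weakest mode (ρ ≈ 0.51) is hard to re-identify in some
group refits, and the result reports how many replicates carried a
low-quality match rather than hiding them; at n = 2000 per group the count
drops to zero.

## Layout

```
R/                  implementation (cohort generator, deconfounding, CCA,
                    mode alignment, bootstrap contrast, genetics, report,
                    pipeline)
inst/extdata/       encoded published hit-count tables and a labeled
                    synthetic reconstruction of subregion-level hit locations
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R   headline-quantity recomputation (see above)
vignettes/methods.Rmd  model, conventions, design decisions, limitations
```
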