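---
title: "Triangulating a biomarker-blood pressure relationship: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating a biomarker-blood pressure relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The scientific problem

Observational studies consistently find that people with low serum
25-hydroxyvitamin D [25(OH)D] have higher blood pressure and more
hypertension, yet randomized trials of supplementation are mostly null. The
classic explanations are confounding (adiposity, lifestyle, outdoor
activity) and reverse causation (hypertensive people go outside less).
Triangulation attacks the question with designs whose bias structures
differ:

1. **Cross-sectional regression** of blood pressure on the
   season-standardized biomarker, adjusted for measured confounders —
   efficient, but vulnerable to residual confounding.
2. **Prospective regression** of follow-up blood pressure on baseline
   biomarker, additionally adjusted for baseline blood pressure — less
   vulnerable to reverse causation.
3. **One-sample Mendelian randomization (MR)**: a genetic risk score (GRS)
   built from variants in vitamin D transport/synthesis/metabolism genes is
   used as an instrument. Genotypes are fixed at conception, so the
   instrument is immune to reverse causation and classical confounding.
4. **Two-sample MR** on published per-SNP summary statistics, with
   pleiotropy-robust estimators (MR-Egger, weighted median, MR-PRESSO).
5. **Non-linear MR** by stratification, probing whether a causal effect
   exists only at low biomarker levels.

If the observational estimates are non-null but the MR estimates are null,
the coherent interpretation is confounding, not causation. `vitdmr`
implements the full battery plus a synthetic-cohort generator, because the
individual-level data such studies use are access-restricted: every stage
here is exercised against a simulated population whose statistical
structure matches what the designs assume.

## The synthetic world

`simulate_cohort()` draws, for each participant:

* **Genotypes**: 19 independent SNPs under Hardy-Weinberg equilibrium
  (dosage = two Bernoulli(eaf) draws). The bundled panel
  (`default_vitd_panel()`) is *synthetic* — frequencies and per-allele
  weights (nmol/L) are invented, but scaled so the weighted score explains
  5.6% of exposure variance at exposure SD 17 nmol/L, the operating point
  of a strong published vitamin D instrument. Real panels can be supplied
  as TSV via `read_snp_panel()`.
* **Exposure**: \(X_i = \mu + \sum_j w_j g_{ij} + \sum_c \gamma_c C_{ic}
  + A\cos(2\pi(d_i-\phi)/365.25) + \varepsilon_i\), truncated to the assay
  range 10–375 nmol/L. The seasonal term is a single-harmonic cosinor
  (amplitude 15 nmol/L, peak near day 200), a deliberate simplification of
  real high-latitude seasonality. The annual-mean exposure
  \(\bar X_i\) (X without the seasonal term) is what drives outcomes.
* **Confounders**: age (uniform 20–80), sex (Bernoulli 0.53), BMI
  (normal 26.9 ± 4.4), a smoking category, and a *latent* standard-normal
  confounder `u` that is never observed. `u` carries the residual
  confounding that survives covariate adjustment; its effects (−6 nmol/L
  per SD on exposure; +2.62 / +1.36 mmHg per SD on SBP/DBP) were calibrated
  once, on a single large cohort, so that the covariate-adjusted
  cross-sectional association under a *null* causal effect is −1.73 mmHg
  SBP and −0.92 mmHg DBP per 25 nmol/L — the magnitude such studies report.
  They were not revisited afterwards.
* **Outcomes**: latent SBP/DBP per wave with three readings per visit
  (within-visit SD 3 mmHg), medication use from a logistic model in latent
  SBP and age, and wave-2 values as wave-1 plus drift and innovation.
  The default causal effect is **zero**; `theta_sbp`/`theta_dbp` set a
  linear effect (mmHg per nmol/L), and `effect_shape = "jshape"` switches
  to a quadratic dose-response centred at 50 nmol/L (curvature 0.004
  mmHg/(nmol/L)²) whose local slope changes sign across the range —
  detectable by stratified MR at n = 20,000.

What the generator does **not** emulate: linkage disequilibrium, population
stratification, imputation uncertainty, genotype batch effects beyond a
label, assay measurement error beyond truncation, and non-random
participation. A green simulation test therefore establishes that the
*machinery* behaves as designed in a world satisfying the instrumental
assumptions — it says nothing about whether real data satisfy them.

## Phenotype rules

All deterministic rules follow the conventions of the emulated study:
per-visit BP is the mean of the last two of three readings; measured
pressures of medicated participants are amended by +10/+5 mmHg (SBP/DBP);
hypertension is SBP ≥ 140 or DBP ≥ 90 or medication use (measured, not
amended, pressures — for medicated participants the distinction is moot);
the biomarker is season-standardized by fitting
\(v = m + a\cos(2\pi d/365.25) + b\sin(2\pi d/365.25)\) and removing the
mean-centred seasonal deviation, which preserves the grand mean exactly
and is idempotent. Standardized values are floored at 0: the cosinor shift
can push assay-floor (10 nmol/L) winter measurements marginally negative,
which is non-physical for an annual average. Categories are half-open:
[0,30), [30,50), [50,75), [75,∞), with 50–74.9 as reference. Missing
lifestyle covariates become an explicit `"unknown"` level that stays in
the model.

Day-of-year uses a 365.25-day period so leap days fold naturally. Whether
the original month-bin or cosinor variant of seasonal standardization was
used in the emulated study is not recoverable; the cosinor is the simplest
model yielding a per-participant annual average.

## One-sample MR

The instrument is the externally weighted score
\(G_i = \sum_j w_j g_{ij}\). Missing panel SNPs are dropped *without*
re-weighting (matching the use of 19 of 21 variants in the emulated
study); missing dosages are imputed at their Hardy-Weinberg expectation
\(2\,\mathrm{eaf}\). The first stage (score → exposure) is estimated in the
measured sub-cohort, the reduced form (score → outcome) in the total
cohort, both adjusted for age, sex, genotyping batch and 20 principal
components. The Wald ratio \(\hat\theta = \hat\beta_y/\hat\beta_x\)
carries the second-order delta-method variance
\(se_y^2/\beta_x^2 + \beta_y^2 se_x^2/\beta_x^4\), treating the two
coefficients as independent. The sub-cohort is *inside* the total cohort,
so this ignores a small positive covariance — a documented limitation
(the emulated analysis does not model it either). CIs are symmetric
normal, not Fieller; for hypertension the ratio of log-odds is
exponentiated (non-collapsibility is not corrected). First-stage strength
is reported as \(R^2\) and \(F = (n-2)R^2/(1-R^2)\) from the unadjusted
simple regression (an adjusted variant is a one-liner on top of
`fit_linear`), with F ≤ 10 flagged weak; instrument independence is
checked by regressing each confounder on the score
(`confounder_balance()`).

## Two-sample MR

All estimators are implemented from their defining formulas and verified
against independent normal-equation / enumeration oracles:

* **Harmonization**: intersect on rsid; swapped or strand-flipped alleles
  flip the outcome beta; palindromic SNPs are dropped when eaf ∈
  [0.42, 0.58] (strand unresolvable, a conventional window — the emulated
  analysis does not state one) and otherwise aligned by frequency; every
  action is logged.
* **IVW**: weighted origin regression with weights \(1/se_y^2\);
  default *multiplicative random effects* (SE inflated by
  \(\max(1,\sqrt{Q/(m-1)})\)) since fixed-vs-random is unstated in the
  emulated analysis; both are exposed.
* **MR-Egger**: weighted regression with intercept after orienting
  exposure effects positive; intercept tests directional pleiotropy under
  InSIDE; t inference with m−2 df and overdispersion factor
  \(\max(1,\hat\sigma)\).
* **Weighted median**: per-SNP ratios with first-order inverse-variance
  weights \((\beta_x/se_y)^2\), interpolating the mid-cumulative weight
  function at 0.5; SE by seeded parametric bootstrap (default 1000
  draws).
* **Cochran's Q**: first-order weights, \(\chi^2_{m-1}\).
* **MR-PRESSO**: leave-one-out IVW residual sum of squares against a
  parametric simulated null (default 1000 draws, configurable); per-SNP
  outlier p-values Bonferroni-corrected at α = 0.05; the corrected
  estimate is exactly `mr_ivw()` on the non-outliers; the distortion test
  compares the raw-vs-corrected shift with shifts from removing random
  SNP subsets of the same size.

Exposure-scale labels (per nmol/L vs per SD of log-biomarker) are carried
as metadata and never converted implicitly.

## Non-linear MR

Two stratifiers, both returning exact partitions with sizes equal up to
remainder (lower strata absorb extras):

* **Residual method**: stratify on the exposure residual after removing
  the genetically predicted component; assumes a constant genetic effect
  within strata.
* **Doubly-ranked method**: rank by instrument, form consecutive
  pre-strata of size K, rank by exposure within each pre-stratum, send the
  j-th exposure-ranked member to stratum j (a final partial pre-stratum
  fills strata 1..r in exposure-rank order; instrument ties break by
  original order). Non-parametric and less sensitive to the constancy
  assumption.

K is unstated in the emulated analysis; the default is K = 4 with a
20-member minimum stratum size. Per-stratum Wald estimates reuse the
delta-method SE. Non-linearity is tested two ways, because the emulated
analysis names no statistic: Cochran's Q across stratum estimates (any
heterogeneity) and an inverse-variance-weighted meta-regression of
stratum estimates on stratum exposure means (monotone trend). Calibration
note: under a linear effect the residual-method Q and both trend tests
reject at ~4–6% at α = 0.05, but the doubly-ranked Q is conservative
(~1%), because the delta SEs slightly overstate the dispersion of
middle doubly-ranked strata; treat a doubly-ranked Q rejection as strong
evidence, and its absence as weak evidence. In the observational arm,
non-linearity is tested with a hand-rolled Harrell restricted-cubic-spline
basis (default 4 knots at the 5/35/65/95 percentiles; 3–5 knots
supported) and a joint Wald test of the non-linear terms.

## Numerical and degenerate-input choices

* Wald/normal 95% intervals throughout (matching symmetric reported CIs);
  logistic fits use IRLS with |Δdeviance| < 1e-8, max 100 iterations, and
  raise a named error on separation (diverging coefficients).
* `wald_ratio()` errors on β_x = 0 and warns when |β_x|/se_x < 1.
* A single-SNP IVW falls back to the Wald ratio with a warning; Egger and
  the weighted median require ≥ 3 SNPs, MR-PRESSO ≥ 4 and ≥ 100
  simulations.
* Monomorphic SNPs are excluded from summary statistics with a warning;
  zero-variance scores, constant confounders and empty exposure categories
  are rejected or skipped with named conditions.
* One master seed fans out to per-stage child seeds (kept below 2³¹), so a
  pipeline rerun is byte-identical and any stage can be rerun alone.

## Known limitations

* The sub-cohort/total-cohort overlap is ignored in the one-sample SE (a
  small anti-conservative omission at 7% overlap).
* The seasonal model is a single harmonic; real seasonality is skewed.
* Confounder marginals are loosely matched to a single published
  descriptive table; their joint distribution is invented.
* At desk-scale sub-cohort sizes (n ≈ 2,000) the cross-sectional design
  has only ~70% power to exclude zero at the calibrated confounding
  magnitude; the power the emulated study enjoyed comes from its n = 5,854.
  This is visible as a deliberately red acceptance assertion.
* The doubly-ranked Q conservatism described above.

## A worked example

```{r example, eval = FALSE}
library(vitdmr)
report <- run_all(run_config(
  sim = sim_config(n_total = 20000, n_subcohort = 2000),
  seed = 42
))
report$summary
```

The summary table juxtaposes the cross-sectional, prospective, one-sample
MR and two-sample MR estimates per outcome — the triangulation pattern to
look for under the default null world is a clearly negative cross-sectional
row with MR rows straddling zero.
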