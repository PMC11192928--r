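# vitdmr

Triangulated observational and Mendelian randomization (MR) analysis of a
serum biomarker — 25-hydroxyvitamin D, 25(OH)D — against blood pressure and
hypertension, as a tested R pipeline.

## Who this is for

Epidemiologists and biostatisticians who want the full battery of designs
used to probe a biomarker–outcome relationship in one reproducible place:

* **Cross-sectional / prospective regression** with the conventional
  phenotype rules: per-visit BP = mean of the last two of three readings;
  +10/+5 mmHg medication amendment; hypertension = SBP ≥ 140 | DBP ≥ 90 |
  medication; cosinor seasonal standardization of the biomarker; four
  exposure categories (<30, 30–49.9, 50–74.9 reference, ≥75 nmol/L) and a
  per-25-nmol/L continuous coding; restricted-cubic-spline non-linearity
  test.
* **One-sample MR** via an externally weighted genetic risk score
  G<sub>i</sub> = Σ<sub>j</sub> w<sub>j</sub> g<sub>ij</sub>, split-sample
  Wald ratio θ̂ = β̂<sub>y</sub>/β̂<sub>x</sub> with delta-method SE
  se<sub>y</sub>²/β<sub>x</sub>² + β<sub>y</sub>²se<sub>x</sub>²/β<sub>x</sub>⁴,
  first-stage diagnostics F = (n−2)R²/(1−R²), and GRS–confounder balance
  checks.
* **Two-sample MR** from per-SNP summary statistics, implemented from
  formulas: allele harmonization (with palindromic-SNP handling), IVW
  (fixed and multiplicative-random), MR-Egger, weighted median, Cochran's
  Q, MR-PRESSO (global, outlier and distortion tests).
* **Non-linear MR** by residual and doubly-ranked stratification with
  per-stratum Wald estimates and heterogeneity/trend tests.
* A **synthetic-cohort generator** (`simulate_cohort()`) standing in for
  the access-restricted cohort data such studies use: HWE genotypes for a
  19-SNP instrument panel, a seasonal exposure in the 10–375 nmol/L assay
  range, measured and *latent* confounders calibrated so the adjusted
  cross-sectional association is ≈ −1.7 mmHg SBP per 25 nmol/L under a
  null causal effect, two survey waves, three BP readings per visit, and
  medication use. Every downstream stage is testable offline.

The bundled SNP panel is **synthetic** (see
`inst/extdata/vitd_panel_synthetic.tsv`); supply a real panel as TSV
(`rsid`, `effect_allele`, `other_allele`, `eaf`, `weight`) via
`read_snp_panel()`.

## Worked example

```r
library(vitdmr)
report <- run_all(run_config(
  sim = sim_config(n_total = 20000, n_subcohort = 2000), seed = 42))
report$summary
```

Output (abridged; mmHg per 25 nmol/L for SBP/DBP, odds ratios for
hypertension, two-sample MR per nmol/L):

```
           stage      outcome estimate  ci_low ci_high       p
 cross_sectional          SBP -1.36050 -2.7003 -0.0207 0.04656
 cross_sectional          DBP -1.26963 -2.0451 -0.4941 0.00133
 cross_sectional hypertension  0.87620  0.7594  1.0110 0.07026
     prospective          SBP  0.13670 -0.6391  0.9125 0.72984
   one_sample_mr          SBP -0.33951 -2.0698  1.3907 0.70054
   one_sample_mr HYPERTENSION  1.01221  0.8468  1.2099 0.89391
   two_sample_mr SBP:IVW (random) -0.00809 -0.0934 0.0772 0.85244
```

Read it as a triangulation: the generator's true causal effect is zero,
yet the cross-sectional rows are negative (built-in residual confounding),
while the prospective and both MR stages straddle the null — the pattern
that distinguishes confounding from causation. The first-stage instrument
here has F = 126.7 (R² = 0.060 at n = 2,000), comfortably past the F > 10
convention. `run_all()` also writes per-stage TSVs, a combined summary
table and a JSON metadata record (seed, settings, versions) to the output
directory; the same seed reproduces every byte.

A CLI wraps the stages:

```sh
Rscript -e 'vitdmr::vitdmr_cli()' simulate --config cfg.yaml --out dir/ --seed 7
Rscript -e 'vitdmr::vitdmr_cli()' all --config cfg.yaml --out dir/ --seed 7
```

## Documentation

`vignettes/triangulation-methods.Rmd` describes the models and their
assumptions, what the synthetic world does and does not emulate, every
tunable parameter with units and defaults, numerical choices, and known
limitations.
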