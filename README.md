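# elncut

Examined-lymph-node (ELN) count, nodal staging accuracy, and the survival
cut point in resected non–small-cell lung cancer.

## The problem

Pathological nodal staging after lung cancer resection depends on how many
lymph nodes were harvested and examined. When few nodes are examined, truly
node-positive patients are declared node-negative (occult nodal disease),
stage-specific statistics migrate, and under-examined patients die sooner.
Two questions follow for registry analysts and thoracic surgical
researchers:

1. **How unreliable is a node-negative call at a given examination depth?**
   If a patient truly harbors $P$ positive nodes among a nodal population of
   $M$, and $n$ nodes are examined without replacement, the observed
   positive count is hypergeometric. With a prior $\pi(p)$ over the true
   count, Bayes' theorem gives the occult-disease probability
   $\Pr(P > 0 \mid K = 0, n)$ — the chance a declared-pN0 patient is truly
   node-positive — as a decreasing function of $n$.
2. **How many nodes are enough?** Per-ELN-count adjusted odds ratios (stage
   migration, logistic regression) and hazard ratios (overall survival, Cox
   regression; reference = one examined node) form effect series that are
   smoothed with LOWESS (bandwidth 2/3) and scanned with the Chow
   structural-break test $F = \frac{(\mathrm{RSS}_p - \mathrm{RSS}_1 -
   \mathrm{RSS}_2)/2}{(\mathrm{RSS}_1 + \mathrm{RSS}_2)/(n-4)}$; the
   survival-series break is the recommended cut point, validated by the
   adjusted hazard ratio of `ELN >= cutpoint` on independent data.

Because the registries behind such analyses are restricted, the package
ships a mechanistic synthetic-registry generator (latent nodal populations,
hypergeometric sampling, proportional-hazards survival with an
occult-disease mortality penalty) so the entire pipeline is reproducible
and testable end to end. See the methods vignette
(`vignettes/eln-cutpoint-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(elncut)

cfg <- pipeline_config(
  mode       = "simulate",
  generator  = generator_config(n_patients = 40000),  # break induced at ELN 16
  validation_n = 15000,
  out_dir    = "elncut_results",
  seed       = 17)
report <- run_pipeline(cfg)
print(report)
```

```
ELN cut-point analysis report
  derivation cohort: n=40000, deaths=20039, ELN median 7 [IQR 4-13]
  per-ELN OR (stage migration) = 1.076; HR (N0 survival) = 0.990
  selected cut point: 16 (series breaks: survival=16, migration=14, mean_positive=22, occult=19)
  dichotomized HR at 16 (derivation): 0.854 (95% CI 0.817-0.892)
  dichotomized HR at 16 (validation): 0.828 (95% CI 0.772-0.888)
```

Reading the output: every extra examined node raises the adjusted odds of
being staged node-positive by ~7.6% (stage migration) and lowers
declared-pN0 mortality by ~1% until the examination threshold; the Chow
scan of the smoothed survival series places that threshold at 16 nodes
(the generator's configured break; the break estimator's jitter is about
±2 across seeds), and patients examined at or above it have ~15% lower
adjusted all-cause mortality, replicated on an independent cohort. All
intermediate artifacts (cohort CSVs, occult-probability table, effect
series, scan tables, adjusted curves, `report.json`) are in
`elncut_results/`.

Individual stages are available as plain functions (`generate_cohort()`,
`occult_table()`, `eln_effect_series()`, `lowess_fit()`, `chow_scan()`,
`select_cutpoint()`, `dichotomize_and_fit()`, ...), and
`inst/scripts/elncut.R` exposes them as command-line verbs
(`simulate`, `occult`, `effects`, `breakpoint`, `validate`, `run`).

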