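# raschdash

Rasch partial credit calibration and interval-level rescoring of QuickDASH
subscales.

## The problem

The QuickDASH is an 11-item upper-extremity patient-reported outcome
measure scored on a five-point Likert scale ("no difficulty" ... "unable").
Its conventional 0–100 composite treats the ordinal item scores as if the
intervals between response options were equal and as if all items measured
one construct. Neither assumption holds in general: the task items (1–6)
and symptom items (9–11) form distinct subscales, and in some conditions —
Dupuytren disease in particular — the two most severe response options are
not distinguishable in trait units (their category thresholds are *close or
disordered*), so summing raw scores distorts measurement.

`raschdash` implements the full measurement pipeline that addresses this:

1. **Mokken scalability screen** — Loevinger's H for item pairs, items and
   the scale (`scale_H()`); H > 0.3 is the entry gate for Rasch calibration.
2. **Partial credit model (PCM)** — marginal maximum likelihood EM
   estimation with a normal latent prior (`fit_pcm()`). For item *i* with
   ordered categories *k* = 0..*m*, the category probability is

   P(X_i = k | θ) = exp( Σ_{j≤k} (θ − δ_ij) ) / Σ_h exp( Σ_{j≤h} (θ − δ_ij) ),  δ_i0 ≡ 0,

   with δ_ij the Andrich step thresholds (logits) and θ ~ N(0, σ²).
3. **Threshold diagnostics and collapsing** — disorder (δ_ik ≥ δ_i,k+1) and
   closeness flags with automatic, iterative category merging
   (`andrich_thresholds()`, `auto_collapse()`), or the published
   condition-specific recodes (`quickdash_recode()`).
4. **Fit diagnostics** — infit/outfit mean squares, sum-score (Orlando–
   Thissen style) item chi-square, Yen's Q3 local dependence,
   limited-information scale indices (CFI/TLI/RMSEA/SRMR), Cronbach alpha,
   smoothed empirical option curves, and item-person targeting summaries.
5. **Crosswalks** — Lord–Wingersky sum-score distributions and
   expected-a-posteriori scoring convert each raw sum to an interval-level
   0–100 score (`build_crosswalk()`, `apply_conversion()`), alongside the
   published condition-specific QuickDASH conversion tables
   (`load_published_tables()`).
6. **Synthetic cohorts** — a seeded PCM response simulator with skewed
   traits, injected threshold disorder and testlet local dependence
   (`sim_spec()`, `simulate_responses()`, `cohort_spec()`, `inject_ld()`)
   so every stage is testable without patient data.

`run_pipeline()` executes stages 1–5 in order and writes a reproducible
report bundle; the numbered scripts under `analysis/` drive the whole
workflow over the reference cohorts.

## Worked example

Score a simulated Dupuytren-like task-subscale cohort with the full
pipeline, collapsing disordered categories automatically:

```r
library(raschdash)

m <- simulate_responses(cohort_spec("dupuytren_tasks", seed = 11))
cfg <- pipeline_config(m, condition = "dupuytren", subscale = "tasks",
                       collapse = "auto")
b <- run_pipeline(cfg)
b$stages$thresholds$merges
#>    item cat_low cat_high
#> 1 DASH1       3        4
#> 2 DASH4       3        4
#> 3 DASH2       3        4
#> 4 DASH5       3        4
#> 5 DASH3       3        4
#> 6 DASH6       3        4
head(as.data.frame(b$crosswalk), 4)
#>   raw_score theta_eap rasch_score
#> 1         6    -2.555           0
#> 2         7    -1.970          10
#> 3         8    -1.497          18
#> 4         9    -1.092          25
```

Every item's "unable" option (internal category 4) merges into "severe
difficulty" (category 3) — the two responses do not represent different
amounts of hand function in this population — and the crosswalk then maps
each modified raw sum (6–24) to an interval-level 0–100 score.

To score real responses exactly as published, apply the printed scoring
rules and reference tables instead:

```r
tabs <- load_published_tables()
apply_conversion(8, tabs$cts_tasks)
#> [1] 16
```

A raw CTS task-item sum of 8 — "nearly asymptomatic" under conventional
scoring — corresponds to an interval-level score of 16 on the 0–100 Rasch
metric.

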