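---
title: "Rasch rescoring of short ordinal scales: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch rescoring of short ordinal scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschdash)
```

# Scope

`raschdash` turns ordinal responses on short patient-reported outcome
subscales — concretely the QuickDASH task items 1–6 and symptom items 9–11
in Dupuytren disease and carpal tunnel syndrome (CTS) — into interval-level
0–100 scores via the partial credit model. This vignette explains the
model, the estimation and diagnostic machinery, the synthetic cohorts used
for validation, and the design decisions taken where the methodology left
genuine choices.

# The measurement model

## Partial credit model

Each item *i* has ordered categories $k = 0, \dots, m_i$ (0 = best, e.g.
"no difficulty"). Given a person's latent trait $\theta$ (here: severity
of hand disability, in logits),

$$
P(X_i = k \mid \theta) \;=\;
\frac{\exp \sum_{j \le k} (\theta - \delta_{ij})}
     {\sum_{h=0}^{m_i} \exp \sum_{j \le h} (\theta - \delta_{ij})},
\qquad \delta_{i0} \equiv 0 .
$$

The $\delta_{ij}$ are the *Andrich thresholds*: the trait values at which
adjacent category probability curves cross. The raw sum score is the
sufficient statistic for $\theta$, which is what makes a sum-score-to-
interval crosswalk possible at all.

All internal arithmetic is 0-based; everything user-facing (CSV files,
conversion tables) uses the 1-based questionnaire coding, so the minimum
questionnaire sum equals the item count (6 for the task subscale, 3 for
symptoms).

## Estimation

`fit_pcm()` maximizes the marginal likelihood under a normal latent prior
(mean fixed at 0 for identification; SD estimated by default, fixable via
`estimate_prior_sd = FALSE` — the methodology we follow does not state
which variant was used, so both are provided). The EM algorithm:

* **E step** — posterior person weights on a fixed quadrature grid of 61
  equally spaced nodes on $[-6, 6]$ logits with renormalized normal
  weights. A deterministic grid keeps every downstream quantity exactly
  reproducible; 61 nodes put adjacent nodes 0.2 logits apart, an order of
  magnitude below the posterior SDs that occur with 3–6 items.
* **M step** — per-item Newton updates of the step parameters in the
  cumulative parameterization $\eta_k = \sum_{j \le k}\delta_j$, whose
  gradient and Hessian involve only category survivor probabilities; the
  Hessian is negative definite, and steps are damped at 2 logits to guard
  the first cycles. The prior SD update is the posterior second moment.
* **Convergence** — maximum absolute parameter change below $10^{-4}$
  logits, at most 500 cycles; the marginal log-likelihood is recorded each
  cycle and must never decrease (tested to $10^{-8}$).

Degenerate inputs are handled explicitly: an unobserved category aborts
with instructions to recode (the model cannot place a threshold for an
empty category), and a latent variance collapsing toward zero (data with
no common trait) is floored at 0.05 with a warning rather than producing
NaNs.

Person scores are expected a posteriori (EAP): posterior mean and SD of
$\theta$ on the same grid. Sum-score EAPs for the crosswalk use the
Lord–Wingersky recursion for $P(S = s \mid \theta)$; by sufficiency they
agree exactly with pattern-level EAPs, which the tests verify.

## Thresholds, disorder, and collapsing

`andrich_thresholds()` flags a step pair as **disordered** when
$\delta_{ik} \ge \delta_{i,k+1}$ and as **close** when the gap is positive
but below a tolerance (default 0.2 logits — the methodology says "close"
without a number, so the tolerance is an explicit knob). Disorder means
two response options do not occupy distinct stretches of the trait: the
scale pretends to more resolution than the population supports.

`auto_collapse()` repairs this iteratively: fit, flag, merge the single
worst category pair anywhere in the scale (most negative gap; ties broken
toward the most severe categories, matching how disordered "severe
difficulty"/"unable" options are merged in practice), refit. An iteration
guard caps total merges at the number of collapsible steps. The
alternative `collapse = "published"` mode of the pipeline applies the
instrument's published condition-specific recodes verbatim instead, so new
data can be scored exactly as prescribed:

* Dupuytren, items 1–6: "unable" is scored like "severe difficulty" (both
  questionnaire score 4).
* CTS, items 1–6: unchanged.
* CTS, items 9–10: "mild difficulty" is scored like "no difficulty";
  item 11 additionally scores "unable" like "severe difficulty".
* Dupuytren, items 9–11: worst pair merged on every item, with a warning —
  the symptom subscale is not recommended in Dupuytren disease.

# Diagnostics

**Mokken screen.** Loevinger's H for a polytomous pair is the observed
covariance divided by the maximum covariance attainable under the items'
marginal distributions (the comonotonic coupling, i.e.
`cov(sort(x), sort(y))`). Item and scale coefficients are ratios of summed
covariances, *not* means of pair coefficients. The acceptance gate is
H > 0.3 throughout. Tests verify the implementation against an exhaustive
enumeration of all couplings with fixed margins on small tables.

**Infit/outfit.** Mean squares of (standardized) item residuals,
acceptance band 0.5–1.7. A design note: evaluating residuals at plug-in
EAP estimates attenuates the mean squares well below 1 on short scales
(the trait estimate absorbs part of each item's own variation — with 6
items, model-consistent data give plug-in values near 0.8, and *no* noise
injection can push outfit past about 1.5 because the refitted item also
absorbs the noise marginally). `infit_outfit()` therefore integrates each
person's squared residual over their trait *posterior* (the E-step
weights). Under the generating model this calibrates the statistics at 1.0
(medians within [0.9, 1.1] across replicates, tested), a uniform-noise
item exceeds the 1.7 flag, and a deterministic (Guttman-type) item falls
below 0.5 when the scale is long enough for a sharp posterior (~12 items).
Flag sensitivity degrades on very short scales — an inherent limit, not an
implementation artifact. Plug-in residuals remain available via
`standardized_residuals()` because Yen's Q3 is defined on them.

**Local dependence.** Q3 is the Pearson correlation of plug-in residual
columns; pairs above 0.2 are flagged. A duplicated or testlet item pair
shows up here (Q3 of 0.3–0.9 in the injection tests) — local dependence,
not item-level misfit, is the signature of redundancy.

**Item chi-square.** Sum-score based (Orlando–Thissen style): observed
category frequencies within each total-score group against model-implied
conditional frequencies from the Lord–Wingersky distribution of the
remaining items; deterministic extreme sums excluded; adjacent cells
pooled to expected counts of at least 5; degrees of freedom
$\sum_s (\text{cells}_s - 1) - (m_i)$ . Type-I calibration is verified by
simulation (rejection rate at $\alpha = 0.05$ within [0.02, 0.10] over 120
replicates of n = 500). With cohort-sized samples even mild misfit yields
p < 0.01, so the p-values are reported raw and read qualitatively.

**Scale-level indices.** A limited-information chi-square over univariate
and bivariate margin residuals with block-diagonal multinomial weighting —
algebraically, summed Pearson statistics over the margin tables with
sparse-cell pooling, so there is no weight matrix to invert and no
singularity fallback to need. No correction for parameter estimation is
applied, which makes the absolute chi-square conservative; the derived
indices (RMSEA, CFI, TLI against an independence baseline with observed
univariate margins, SRMR as the RMS difference of observed vs
model-implied inter-item correlations) are the quantities interpreted
against the acceptance rules (CFI ≥ 0.950, TLI ≥ 0.950, RMSEA < 0.060,
SRMR ≤ 0.080). Calibration and a two-dimensional misfit probe are both
tested.

**Option curves and targeting.** `empirical_option_curves()` smooths each
option indicator against the EAP estimates (local-linear, Silverman
bandwidth floored at 0.3 logits) on the same grid as the model curves so
both can be superimposed; agreement is tested within ±0.8 logits of the
trait center, because outside one trait SD the EAP shrinkage displaces
the empirical curves systematically. `item_person_map()` reports the
trait histogram, all thresholds, the targeting gap (mean person minus
mean threshold), trait skewness, and floor/ceiling percentages.

# Crosswalks

For each attainable raw sum $s$, $\mathrm{EAP}(\theta \mid S = s)$ is
computed on the quadrature grid, then rescaled linearly so the endpoints
map to 0 and 100 and rounded half-up — the only convention consistent
with integer endpoint rows; whether intermediate values were rounded
before or after rescaling in the printed reference tables is not
documented, and only the endpoints are verifiable. Conversion tables are
condition- and subscale-labelled, and `apply_conversion()` refuses
mismatched labels: the Dupuytren and CTS metrics are not interchangeable.
The four published QuickDASH reference tables ship in
`inst/extdata/` (provenance `"published"`, no logit column).

# Synthetic cohorts

The generator draws $\theta$ from a normal or skew-normal distribution
(the latter via the half-normal construction), adds optional testlet
components ($\theta + \gamma u$ with $u$ standard normal per person and
testlet), and samples categories from the PCM. One root seed spawns
separate child streams for trait, testlet and response draws, so toggling
a testlet (or setting $\gamma = 0$) leaves the other draws bit-identical.
Threshold disorder is injected simply by writing reversed adjacent steps
into $\delta$ — the PCM generates from them as-is.

The four reference cohorts mirror the study populations structurally:

* `cts_tasks` / `cts_symptoms` — n = 1851, trait N(0, 1), item locations
  spread across the trait (centers −1.2 to +1.3, ordered steps 1 logit
  apart): well-targeted, no floor/ceiling effects.
* `dupuytren_tasks` / `dupuytren_symptoms` — n = 731, negatively skewed
  trait (skew-normal, shape −4, rescaled to mean 0, SD 1.4), item
  locations about 1 logit above the trait mean, and the two most severe
  steps reversed (offsets −2.05, 0.05, 1.55, 0.45) so the top thresholds
  are disordered on every item.

Two generator constants deserve comment. First, category observability:
the constants were fixed at design time so that every category of every
item appears with near-certainty at the cohort sizes, because an
unobserved category is a hard precondition failure for the PCM fit (the
real cohorts did observe all categories). Second, the deep first step
(−2.05) keeps part of the lower trait range measurable; without it the
mistargeting compresses the entire lower tail of the trait into a floor
lump of identical EAPs, and the negative skew of the *trait* disappears
from the *estimates* entirely. Even so, EAP skewness in the mistargeted
cohort is only mildly negative (about −0.05 to −0.19 across seeds) while
the generating trait skewness is −0.85: mistargeting destroys precisely
the tail information that carries the skew. Tests therefore assert strong
negative skew on the trait and the correct sign on the estimates.

What the simulator does **not** emulate: real response styles (central
tendency, acquiescence), differential item functioning, missingness, and
the content-driven misfit of real items (e.g. task items that stop
discriminating at high function). Passing tests on these cohorts
demonstrate that the machinery is correct under its own assumptions, not
that any real instrument fits.

# Problem sizes used in validation

Simulation-based checks use sizes chosen to make sampling noise
negligible relative to the tested tolerances while keeping the suite
quick: parameter recovery and diagnostic calibration at n = 2000 (step
RMSE ≤ 0.1 logits; 24 free steps put the statistical floor near 0.08, so
well-observed moderate thresholds, centers ±0.8 with steps ±1, are the
appropriate recovery design); chi-square type-I calibration over 120
replicates of n = 500; infit/outfit medians over 200 replicates of
n = 400; option-curve consistency at n = 4000; oracle comparisons
(coupling enumeration, pattern enumeration, fine-grid integration) on
instances small enough to enumerate exhaustively.

# Known limitations

* Rating scale and generalized (free-slope) models, conditional ML
  estimation, and weighted likelihood (WLE) person estimates are out of
  scope; EAP with a normal prior is the single scoring rule.
* The limited-information chi-square is conservative in absolute terms
  (no parameter-uncertainty correction); compare models via the derived
  indices, not the raw statistic.
* Infit/outfit flags lose sensitivity on 3-item scales (wide posteriors);
  rely on Q3 and the scale indices there.
* Crosswalks assume complete responses; the package deliberately performs
  complete-case filtering and no imputation.
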