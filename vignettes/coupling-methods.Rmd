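---
title: "Coupling visual-function outcomes with CRITIC weights: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling visual-function outcomes with CRITIC weights: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visioncouple)
```

## The problem

Anisometropic amblyopia degrades several visual functions at once:
best-corrected acuity of the amblyopic eye, the balance of interocular
rivalry (a proxy for suppression), cortical control of perceived eye
position, and stereopsis. After months of dichoptic push–pull training
these functions improve to different degrees in different children, and the
per-subject improvements in one function correlate only weakly with the
others. A single examination — classically acuity — is therefore a poor
summary of what treatment achieved. This package builds a composite: each
subject's four pre/post difference scores are combined with *objective*
weights derived from the data itself.

## Measurement scales

* **Visual acuity** is stored in logMAR; decimal chart readings are
  converted as $\mathrm{logMAR} = -\log_{10}(\mathrm{decimal})$ on ingest
  (the standard chart spans decimal 0.1–2.0, i.e. logMAR 1.0 to −0.3, in
  0.1 steps). Lower is better.
* **Binocular rivalry balance point (BRBP)** is an 8-level per-eye ladder of
  signal/noise dot proportions under dichoptic viewing:
  (100, 0), (85, 15), (70, 30), then 10 percentage points traded per level
  to (20, 80) at level 8. Levels 4–7 are the arithmetic continuation of the
  explicitly defined rungs. The cohort indicator is the *interocular gap*
  $|L - R|$ per phase: a balanced visual system has a small gap. We use the
  absolute gap rather than a signed (amblyopic-minus-fellow) difference
  because the eye labels carry no information for a composite score and the
  absolute form is invariant to relabelling; a signed alternative would be
  equally defensible had per-eye laterality been retained in downstream
  analyses.
* **Perceptual eye position (PEP)** is the angular deviation (degrees)
  between perceived and actual fixation alignment, measured horizontally
  and vertically as non-negative magnitudes. Only the *horizontal*
  component is coupled: in the motivating cohort the vertical component did
  not change significantly with treatment, so it is parsed, screened and
  reported but never weighted.
* **Stereoacuity** is coded 4/3/2/1/0 for thresholds of 100/200/300/400
  arcseconds and absent stereopsis; the test has exactly four plates, so
  other thresholds are rejected rather than interpolated. Higher is better.

Difference scores are **post minus pre**. With these scales, improvement is
negative for `d_va`, `d_brbp` and `d_hpep` and positive for `d_sa` — the
sign pattern visible in the published cohort means (−0.38, −1.48, −0.60,
+0.85). The orientation step before coupling negates the three cost-type
indicators so that larger always means better.

## The CRITIC chain

Given the $m \times n$ difference matrix $X = (x_{ij})$:

1. Z-score standardize each column:
   $x^*_{ij} = (x_{ij} - \bar{x}_j) / s_j$, with the sample ($n-1$) SD.
2. Variation (contrast-intensity) coefficient $v_j$ — see below.
3. Pearson correlation matrix $R = (r_{kl})$ of the standardized columns
   (identical to raw-data correlation; a test asserts this invariance).
4. Independence (conflict) coefficient
   $\eta_j = \sum_{k=1}^{n} (1 - |r_{kj}|)$, the self-term contributing 0.
   We read the sum literally over all $k$, so $\eta_j \in [0, n-1]$.
5. Information volume $D_j = |v_j|\,\eta_j$ (default; see magnitude policy).
6. Weights $\omega_j = D_j / \sum_j D_j$, summing to 1.

### The variation-coefficient convention

The textbook coefficient of variation is $v_j = s_j/\bar{x}_j$
(`convention = "eq"`). The published parameter table of the motivating
cohort, however, prints values that are exactly $\bar{x}_j/s_j$ — e.g.
−0.38/0.26 = −1.46 — the reciprocal. Both are implemented behind the
`convention` switch; the default is `"table"` because it reproduces the
printed column exactly, and because for difference scores with means near
zero the reciprocal form is the numerically tamer of the two. The
discrepancy is surfaced in the tidy output rather than silently resolved.

### The magnitude policy

Three of the four published variation coefficients are negative (negative
mean differences), so a literal product $v_j \eta_j$ would yield negative
information volumes and negative weights, while published weights are
positive. The default policy therefore takes $|v_j|$ in step 5 —
dispersion relative to the mean carries information regardless of the
improvement direction, which the orientation step handles separately. A
`"signed"` mode is retained for sensitivity experiments.

### Non-reproducibility of the published weights

The published weights (0.2154, 0.2575, 0.1724, 0.3547) are **not**
recoverable from the published summary table under either convention or
magnitude policy: the full chain applied to the printed two-decimal
summaries gives (0.4266, 0.2263, 0.1439, 0.2032), as asserted by a test.
The original weights were evidently computed from the raw per-subject
data, possibly after a min–max rescaling of the raw matrix as in the
original CRITIC literature; without the raw data the question cannot be
settled. Consequently `reference_cohort()$weights` is a documented
constant, never an implicit default of `run_critic()`.

## The coupling index

No closed formula for the published per-subject coupling index was ever
stated, so the package defines its own and treats the published values as a
qualitative reference only. Default: orient the difference scores
(cost-type negated), min–max normalize each indicator across the cohort,
$u_{ij} = (x_{ij} - \min_i x_{ij}) / (\max_i x_{ij} - \min_i x_{ij})$, and
combine $CI_i = \sum_j \omega_j u_{ij} \in [0,1]$. Min–max is the
normalization native to the CRITIC literature and produces scores on the
same [0, 1] scale as the published ones (0.13–0.52). A cohort Z-score
normalization is available as an alternative. The index is monotone in
every oriented component, invariant to positive rescaling of any indicator,
and decomposes exactly into per-indicator contributions (`w_u_*` columns).

What *is* checked against the published account is the ordering it
narrates: the subject with the largest multi-indicator improvement (S1)
attains the maximal index, and the mildly amblyopic S5 — nearly cured but
with little room to improve — scores below S4. Both hold under the default
configuration whether the weights are fitted to the validation cohort or
fixed at the published reference values. Baseline severity influences the
index only through the difference scores; no pre-treatment covariate is
added, because the published account motivates exactly this
difference-based design (a future composite of post-treatment status plus
difference is explicitly out of scope).

## The validation fixture

`validation_cohort()` ships the eight held-out subjects (16 examination
records). One cell — S1's pre-treatment right-eye BRBP level — is not
legible in the source table and is stored as missing and flagged on read;
the package imputes nothing by default. `fill_missing = TRUE` substitutes
level 8, a *synthetic, documented* completion chosen to be consistent with
the narrative that only S1's left eye improved (4 → 7) while the
post-treatment right eye sat at level 8; it also makes S1's gap difference
−3, matching the improvement pattern the narrative describes. Analyses of
the fixture that need complete cases state this choice.

## The synthetic-cohort generator

Raw per-subject data were never deposited, so the generator emulates the
published second-order structure: draws are multivariate normal with the
published 4 × 4 correlation (via the Cholesky factor of the implied
covariance), rescaled to the published SDs (0.26, 2.02, 1.31, 1.26) and
means (−0.38, −1.48, −0.60, +0.85) of the n = 46 training cohort. Those
published values *are* the generator defaults; nothing about them is
tuned. A Gaussian copula is the minimal assumption given that only first
and second moments were published.

`mode = "discretized"` snaps draws to the legal grids (0.1 logMAR steps;
integer BRBP-gap differences clipped to [−7, 7]; integer stereo-level
differences clipped to [−4, 4]) by post-hoc rounding rather than ordinal
latent thresholds — simpler, and adequate at these SDs: a test asserts the
discretized correlations stay within 0.1 of the continuous targets at
n = 10 000. `simulate_cohort()` additionally realizes paired examination
records: pre-treatment values are drawn uniformly from the clinically legal
grids (logMAR 0.1–1.0, per-eye BRBP 1–8, PEP 0–3°, stereo 0–4) subject to
feasibility of the subject's difference, and post = pre + difference;
differences no legal pre value can accommodate (practically only
`d_hpep` < −3°) are clipped first, so recomputing difference scores from
the records returns exactly the clipped matrix.

What the generator does **not** emulate: treatment-duration, age and
adherence effects; floor/ceiling asymmetries of real clinical scales
(clipping is symmetric); any non-Gaussian tail behaviour; and within-eye
BRBP dynamics (only the gap is structured — eye pairs realizing a gap are
uniform). Passing recovery tests therefore shows the pipeline is correct
and stable under the published moment structure, not that real cohorts are
Gaussian.

## Numerical choices and problem sizes

* Sample ($n-1$) SDs everywhere; two-sided p-values; no multiple-testing
  correction (none was applied in the motivating analysis) and no
  nonparametric alternatives.
* Degenerate inputs fail loudly with typed conditions: zero-variance
  columns (`vc_degenerate_error`, naming the column), unpaired subjects
  (`vc_pairing_error`), illegal scale values (`vc_domain_error`),
  non-positive-definite correlation targets (`vc_spec_error`, suggesting a
  nearest-PD repair).
* Cohorts below m = 3 are rejected — correlation is undefined — rather
  than padded.
* Ties in the coupling ranking break lexicographically by subject id, so
  reports are deterministic.
* Correlation entries are clamped to [−1, 1] against floating-point
  excursions; weight normalization is exact to 1e−12 by construction.
* Test problem sizes: property suites run on random 8 × 4 to 30 × 6
  matrices; moment-recovery checks use n = 10 000 (±0.05 on means, ±3% on
  SDs, ±0.03 on correlations — tolerances set from the sampling error at
  that n); the Monte-Carlo band for the paired-t magnitude uses 200 seeds
  at the design size n = 46. The whole suite runs in a few seconds.

## Limitations

* The composite is cohort-relative: min–max normalization makes a
  subject's index depend on who else is in the cohort. Comparable scores
  across studies would need a fixed normalization reference.
* With very small cohorts (the 8-subject fixture) CRITIC weights are
  noisy; an indicator that barely moved in that cohort receives a near-zero
  weight regardless of its clinical importance. Fixed reference weights are
  the better choice there, and both options are exposed.
* The published weights and coupling-index values cannot be validated
  quantitatively without the raw data; only their qualitative ordering
  claims are testable, and those are the ones tested.
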