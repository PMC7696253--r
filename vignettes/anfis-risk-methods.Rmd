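---
title: "Methods: predictive safety-risk assessment with a Takagi-Sugeno ANFIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predictive safety-risk assessment with a Takagi-Sugeno ANFIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfisrisk)
```

## The assessment model

`anfisrisk` implements a predictive occupational-safety risk assessment
workflow for multi-site expert surveys, of the kind run on construction
projects. One expert per site rates every identified risk on four
parameters — probability of occurrence, severity of the resulting injury,
duration of exposure, and (lack of) detectability — on a five-level
linguistic ladder (Very Low ... Very High). The ladder maps to raw odd
integers $\{1,3,5,7,9\}$ and, by min-max normalization
$x_n = (x - x_{\min})/(x_{\max} - x_{\min})$, to
$\{0, 0.25, 0.5, 0.75, 1\}$. Each level also carries a triangular fuzzy
number on the normalized axis — $(0,0,0.25)$, $(0,0.25,0.5)$,
$(0.25,0.5,0.75)$, $(0.5,0.75,1)$, $(0.75,1,1)$ — used as the membership
functions of the fuzzy predictor.

The composite **risk magnitude** of one assessment is multiplicative:

$$RM = p \times s \times e \times d,$$

spanning $[1, 9^4] = [1, 6561]$ on the raw scale and normalized onto
$[0,1]$ by the same min-max rule. Four evaluation bands partition the
magnitude axis and mandate an action:

| band | raw range | action |
|---|---|---|
| Negligible | $[1, 16)$ | Accept |
| Minor | $[16, 81)$ | Mitigate |
| Major | $[81, 256)$ | Mitigate |
| Critical | $[256, 6561]$ | Eliminate |

Two conventions about these bands deserve a note. First, the widely
tabulated normalized cutpoints 0.002 / 0.012 / 0.038 are *truncations*
(toward zero, 3 decimals) of the exact normalizations $15/6560$,
$80/6560$, $255/6560$ — the last of which rounds to 0.039, not 0.038.
Second, only the exact cutpoints classify consistently with the raw
intervals for every integer magnitude (raw 255 is Major, but its
normalization 0.0387 exceeds the truncated cutpoint 0.038). The package
therefore defaults to the exact cutpoints
(`evaluation_bands(style = "exact")`) and offers
`style = "printed"` for strict agreement with the truncated display
values. Worked-data magnitude columns, by contrast, are conventionally
*rounded*; comparisons against published 3-decimal magnitude tables use
round-half-away-from-zero (`round_half_up()`), not base R's
round-half-to-even.

## The ANFIS predictor

The predictor is a first-order Takagi-Sugeno adaptive neuro-fuzzy
inference system built from scratch, as a five-layer network:

1. **Fuzzification** — triangular memberships $\mu_{j,k}(x_j)$ of each
   normalized input $x_j$ in each of its membership functions.
2. **Firing strengths** — one rule per grid-partition cell (every
   combination of one MF per input); $w_r = \prod_j \mu_{j,r_j}(x_j)$.
3. **Normalization** — $\bar w_r = w_r / \sum_r w_r$ (asserted to sum to
   one; the shoulder MFs guarantee every point of the unit cube fires at
   least one rule).
4. **Weighted consequents** — $\bar w_r f_r$ with
   $f_r = m_r^\top x + p_r$ (order 1, default) or $f_r = c_r$ (order 0).
5. **Sum** — the predicted normalized magnitude $\sum_r \bar w_r f_r$.

**Hybrid training.** Per epoch, the consequent coefficients are solved
*globally* by ridge-regularized linear least squares on the layer-4
design matrix (each rule contributes columns
$\bar w_r x_1, \ldots, \bar w_r x_d, \bar w_r$), and the premise MF
parameters then take one gradient-descent step on the squared training
error with consequents held fixed. The premise gradient is computed by
central finite differences — the triangular-MF loss is piecewise smooth
and the step is small — and each updated MF is clamped to
$a \le b \le c$ with support inside $[-0.25, 1.25]$; a step that would
open a coverage hole is rejected. Training stops at `epochs` or when the
training-RMSE improvement drops below `tol` (default $10^{-6}$); the
least-squares step is optimal given the premises, so training RMSE is
non-increasing across epochs when premises are frozen.

**Why ridge is not optional.** For partition-of-unity premises the
order-1 design is structurally collinear: the weighted input columns of
all rules sum to the plain input column, and the weighted intercepts sum
to the constant column. The unregularized normal equations are therefore
singular (or numerically so), and the default `ridge = 1e-6` selects the
unique regularized solution; any singular solve falls back to a minimal
automatic ridge with a warning.

### Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `mfs_per_input` | 3 | 81 rules / 405 order-1 coefficients. With surveys of a few hundred records, 5 MFs per input (625 rules, 3125 coefficients) is hopelessly underdetermined; `mfs_per_input = 5` remains available and reproduces the linguistic-ladder TFNs exactly. |
| `consequent_order` | 1 | linear rule outputs, the standard Sugeno form. |
| `epochs` | 30 | with early stopping, runs typically cease after a handful of epochs. |
| `premise_step` | 0.01 | conservative; `0` freezes premises (pure least squares), which already fits the magnitude surface near-exactly. |
| `ridge` | 1e-6 | see above. |
| `tol` | 1e-6 | plateau threshold on training RMSE. |

The default initialization (evenly spaced triangles, zero consequents) is
deterministic, so default runs are bit-reproducible; the seed only
controls optional initial-mode jitter (`init_jitter`) and site sampling in
`split_by_site()`.

**Generalization protocol.** Train/test splitting is at *site* level —
whole sites are held out — because the deployment question is predicting
risks on a site the model never saw. The default 7:3 site ratio on a
29-risk, 10-site survey gives 203 training and 87 test records.

**Extrapolation.** Predictions are clipped to $[0,1]$ before band
classification (the network is not constrained to the target range
outside the data); the clipped count is attached to the prediction
vector.

## Why a multiplicative four-parameter score is learnable here

In normalized coordinates the magnitude surface is
$\big(\prod_j (1 + 8x_j) - 1\big)/6560$ — a multilinear polynomial.
Piecewise-multilinear blending of linear consequents over a triangular
grid partition represents such functions almost exactly, which is why a
3-MF order-1 model trained on a few hundred noiseless samples reaches
held-out RMSE below $10^{-3}$, and why an ordinary least-squares fit on
the four ratings (the `linear_baseline()`) — which cannot represent the
interaction terms — is systematically worse. The test suite asserts the
qualitative ordering (ANFIS beats OLS on a common split), not any
particular published metric value.

## The synthetic rating generator

`generate_ratings()` emulates the statistical structure the pipeline
assumes: each risk has a latent profile (a center level 1-5 per
parameter), every site's expert rates each risk at its center shifted one
ladder level up or down with probability `rater_sd` (clamped to the
ladder), and the record's magnitude is computed from the jittered
ratings. Noise is *discrete ladder jitter*, not Gaussian: ratings are
ordinal and observed data contain only ladder values. Defaults (29 risks,
10 sites, `rater_sd = 0.1`) mirror the bundled case study's dimensions;
profiles are sampled uniformly over the ladder unless given, and a
`"case_study"` preset reuses the bundled site's marginal level
frequencies. With `rater_sd = 0` all sites agree exactly and Cronbach's
alpha is 1.

What the generator does **not** emulate — and hence what passing tests do
not establish about real surveys: correlated rating errors within an
expert, parameter-specific disagreement (severity is typically less
contested than detectability), site-level systematic biases, and missing
or even-valued responses. Synthetic results demonstrate that the pipeline
recovers structure it assumes; they cannot certify field performance.

## Metrics and consistency

* `rmse()`, `mape()`, `r_squared()` follow their standard definitions;
  MAPE is reported as a fraction and excludes zero-actual records (the
  all-minimum rating row has magnitude exactly 0) with a logged tally.
* The determination coefficient is implemented as the squared Pearson
  correlation of actual and predicted magnitudes.
* `cronbach_alpha()` is the classical
  $\frac{k}{k-1}\left(1 - \sum_i \sigma^2_i / \sigma^2_T\right)$ on a
  cases-by-items matrix. For inter-rater consistency, put risks in rows
  and raters (sites) in columns. The all-constant matrix — perfect
  agreement — is the $0/0$ limit and returns 1; other zero-variance
  inputs are errors.
* `compare_parameterizations()` contrasts the traditional two-parameter
  ranking (probability x severity, normalized over $[1,81]$) with the
  four-parameter ranking, reporting tie-group structure: two-parameter
  scoring routinely ties risks that exposure and detectability separate,
  which is the practical argument for the richer score.

## Numerical and design choices

* **Rating encodings.** Ratings are accepted as verbal anchors, raw odd
  integers, or normalized values; off-ladder numerics (raw 4, normalized
  0.3) are rejected with the offending record named, never interpolated.
  The value 1 is valid in two encodings (raw level 1, normalized level
  5); auto-detection prefers the raw reading, and files on the normalized
  scale should pass `encoding = "normalized"`.
* **Detectability's reversed anchors.** "Very High" detectability means
  the hazard is easy to notice and contributes *least* risk; the reversal
  lives only in the verbal-anchor lookup, so the numeric ladder is shared
  and a larger normalized value always means more risk.
* **Aggregation across sites** is the arithmetic mean of normalized
  magnitudes by default (median and max available); published summaries
  of this kind print aggregated values without stating the rule, and the
  mean is the least surprising choice.
* **Ranking ties** share the smaller rank (competition ranking), with
  stable input order among tied rows.
* **Bundled case-study data.** The package ships the worked single-site
  assessment table (29 records), the 29-risk register, and the published
  per-risk summary. The loader revalidates the assessments on every load
  (recomputed magnitudes must match the published column at 3 decimals).
  The published summary is internally inconsistent for four rows — their
  printed band contradicts the band table applied to their printed
  aggregated magnitude — and `classification_discrepancies()` enumerates
  them (SR12, SR13, SR24, SR27) rather than replicating the
  inconsistency. Two of them (SR12, SR27) were also relegated to the
  bottom of the published ranking regardless of their aggregated values;
  `rank_risks()` instead ranks every risk by magnitude, deterministically.

## Problem sizes used in the test suite

The suite exercises desk-scale instances chosen to make every property
checkable by an independent oracle: hand-computable 2-rule networks,
exhaustive classification over all 6561 raw magnitudes, least-squares
solves on at most 8 rules and 30 samples against explicit normal
equations, surface-approximation runs with 500 training and 500 held-out
samples, and full 29 x 10 synthetic pipelines. All of it runs in seconds
on one core.

## Known limitations

* Mamdani inference, non-triangular membership families, user-defined
  numbers of ladder levels, and subtractive-clustering rule bases are out
  of scope.
* The premise gradient is a plain first-order step; no line search or
  adaptive learning rate. In practice the least-squares consequent solve
  does nearly all the work for this target family.
* The model offers no mitigation-strategy optimization beyond the three
  mandated actions, and no reliability weighting of individual experts.
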