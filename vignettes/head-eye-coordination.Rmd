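---
title: "Measuring directional head–eye coordination with transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring directional head–eye coordination with transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordte)
```

## The model

Eye rotation `X_t` and head rotation `Y_t` (yaw, degrees, 90 Hz in the
reference setting) are treated as two coupled stochastic processes. Head–eye
coordination shows up as predictive information flowing between them: if
preparatory head motion precedes the gaze shift, the head's immediate past
`Y_{t−1}` improves prediction of the current eye sample `X_t` beyond what the
eye's own past `X_{t−1}` already provides. Transfer entropy measures exactly
that surplus:

$$TE_{Y \to X}(l, k) = H(X_t \mid X_{t-1}^{(k)}) - H(X_t \mid X_{t-1}^{(k)}, Y_{t-1}^{(l)}),$$

in bits, non-negative, bounded above by the *entropy ceiling*
$H(X_t \mid X_{t-1}^{(k)})$, and asymmetric in the two channels. The package
defaults to history lengths $l = k = 1$, the common choice for these data;
`transfer_entropy()` accepts general $(l, k)$.

The directional summary statistics are

$$UID_{Y \to X} = TE_{Y \to X} - TE_{X \to Y}, \qquad
  NUID_{Y \to X} = NTE_{Y \to X} - NTE_{X \to Y},$$

with the normalized transfer entropy

$$NTE_{Y \to X} = \frac{TE_{Y \to X} - \mu_{Y^S \to X}}{H(X_t \mid X_{t-1})},$$

where $\mu_{Y^S \to X}$ is the mean TE from *shuffled-source* surrogates to
the original target — a direct estimate of the finite-sample bias of the
plug-in estimator under no coupling — and the denominator rescales the
corrected flow by the most that could possibly flow. A positive UID/NUID
reads "head leads eye"; for NUID the zero point itself is not meaningful
(both directions are bias-corrected independently), only the ordering is:
larger values mean a stronger head-leads-eye tendency.

### Assumptions

* Within a trial the joint process is treated as stationary; each trial gets
  its own discretization and surrogate null.
* With $l = k = 1$, order-shuffling surrogates is an adequate null: the
  shuffle destroys all temporal structure while preserving the one-sample
  marginals the estimator conditions on.
* Whether the eye channel is head-relative or world-relative gaze is a
  property of the recording, not of the method; the package treats the two
  channels symmetrically and leaves that labelling to the user.

## Probability estimation

The estimator is the histogram plug-in (maximum likelihood): `discretize()`
bins each channel into `B` symbols, `joint_distribution()` counts the
`(x_t, x_{t-1}^{(k)}, y_{t-1}^{(l)})` tuples, and entropies are computed from
the empirical cell probabilities with the $0 \log 0 = 0$ convention. The
plug-in is the canonical baseline for short behavioural series; its upward
bias on finite samples is precisely what the surrogate subtraction in NTE
and the surrogate null behind λ correct for, which is why no analytic bias
correction (Miller–Madow, shrinkage) is layered on top.

Tunable parameters, defaults, and reasons:

| parameter | default | meaning / rationale |
|---|---|---|
| `alphabet_size` (B) | 8 | histogram bins per channel; coarse enough that a 3-minute trial (16,200 samples) populates the $8^3$ joint cells, fine enough to resolve the yaw range |
| `scheme` | `equal_width` | bins span `[min, max]` per trial per channel, right-open except the last; `quantile` available for heavy-tailed channels (duplicate quantile edges are merged, shrinking B) |
| `l`, `k` | 1, 1 | one-sample histories; the conventional operating point for these data |
| `chebyshev_k` | 6 | the 6-Sigma decision rule; distribution-free confidence $1 - 1/36 = 97.2\%$; 4.47 is the 95% floor |
| `n_surrogates` | $\lceil 2/\alpha\rceil - 1 = 71$ | two-sided surrogate count for $\alpha = 1/36$ |
| `max_gap` | 0.1 s | longest missing run (≈9 samples at 90 Hz) filled by linear interpolation — the standard blink-artifact window; longer dropouts are excluded pairwise |
| `scale_factor` | 360° | fixed in `coord_amount()`: the largest possible absolute difference of two rotation samples; not configurable in comparable outputs |

A constant channel collapses to a single symbol (B = 1); its entropy ceiling
is 0, transfer entropy into it is 0, and NTE is defined as 0 with a
`degenerate` flag rather than 0/0.

## Surrogate conventions and reproducibility

Two distinct surrogate conventions coexist deliberately, each following the
definition of the statistic it serves:

* the **UID null ensemble** shuffles *both* channels independently (the null
  is "no temporal relation in either direction"); a `shuffle = "source"`
  option restricts to head-only shuffling;
* the **NTE bias term** and single-direction TE significance shuffle the
  *source only*, leaving the target's autocorrelation intact, since the
  quantity being corrected is flow into an unchanged target.

Every ensemble draws its per-surrogate sub-seeds deterministically from the
configuration's master seed — and from nothing else, in particular not from
the channel labels. Consequences worth relying on: reruns are bit-identical;
`compute_nuid()` of a series against itself is exactly 0; and swapping the
two channels exactly negates UID and NUID.

The Chebyshev bound is distribution-free and therefore conservative: under
the shuffled null the observed false-alarm rate of `λ > 6` is far below the
nominal $1/36$. The package reports the unrounded confidence
($1 - 1/k^2$; 97.22% at $k = 6$). Mathematically each NTE lies in $[-1, 1]$
(both TE and its bias estimate lie between 0 and the ceiling); a tighter
$[-0.5, 0.5]$ range is sometimes quoted for this normalization but is not
forced by the formula, so the package asserts only the provable bound and
records, rather than clips, anything outside the narrower band.

## The simulator

`simulate_pair()` provides ground-truth-coupled pairs for calibration and
power analysis; its defaults are the reference study conditions — 16,200
samples, i.e. 3 minutes at 90 Hz, one driving trial.

* `binary_copy` — i.i.d. uniform binary source, target a lag-shifted copy:
  the coupled direction carries exactly 1 bit in the large-sample limit and
  the reverse 0, giving an analytic anchor for the estimator.
* `gaussian_ar` — source AR(1) (coefficient 0.5), target AR(1) plus
  `coupling` × lagged source plus Gaussian noise (sd 0.2 by default, with
  coupling 0.8 as the "strong" operating point): a linear
  stochastic-coupling testbed with a tunable signal-to-noise ratio.
* `headeye_like` — a slowly wandering near-unit-root head yaw (sd ≈ 5°),
  an eye channel following it at a lag through a gain, plus Poisson-timed
  (≈1/s) saccade-like step offsets bounded at ±30° and measurement noise:
  qualitatively shaped like driving data, used for plausibility rather than
  physiology.

What the simulator does *not* emulate: vestibulo-ocular reflex dynamics,
smooth pursuit, task-locked gaze strategies, non-stationary attention
drifts, or tracker noise spectra. Passing the recovery tests therefore shows
the estimator detects and signs lag-coupling of realistic strength at trial
length — it does not certify behaviour on any particular physiological
recording.

## Numerical and design choices

* Plug-in conditional entropies are differences of joint and margin
  entropies on the same count table; tiny negative differences from float
  cancellation are clamped to 0, preserving $0 \le TE \le$ ceiling.
* `discretize()` uses right-open bins with the last bin closed, so the
  maximum lands in the top bin; `quantile` edges use the default type-7
  empirical quantiles.
* `coord_amount()` caps its mean squared difference at $10^{-12}$ deg² and
  flags the result degenerate, keeping the decibel value finite for
  identical traces.
* Driving performance inverts the mean *absolute* acceleration of the speed
  trace (km/h → m/s, first differences over timestamp deltas): a signed mean
  is ≈0 over any speed-keeping trial and its inverse meaningless. An RMS
  variant sits behind `method = "rms"`. Traces with average acceleration
  below $10^{-9}$ m/s² return a flagged, capped value.
* Kendall correlation is tau-b (tie-corrected) with asymptotic two-sided
  p-values; Spearman uses average ranks. Both matter because cohort tables
  are printed at 2 decimals and full of ties.
* Cohort display tables multiply the information measures by $10^2$ and
  round to 2 decimals — the conventional printing scale; stored values stay
  unscaled.

## The packaged reference cohort

`cohort_te()`, `cohort_uid()` and `cohort_nuid()` carry the published
per-trial values of a 12 × 4-trial VR driving study on the ×10⁻² scale.
`fixture_check()` recomputes from them: the 48 UID differences (they
reproduce the published UID table within 0.01 — the printed TE inputs carry
±0.005 each, so their difference is only defined to one unit in the last
place), the eye→head TE column mean (1.87, printing as 1.9), the
two-direction ANOVA ($F(1, 94) = 80.27$ against the published 80.25), and
the NUID–performance correlations. Pearson (0.316) and Kendall (0.267)
round to their published 0.32 and 0.27; Spearman computes to 0.3996, which
rounds to 0.40 where 0.41 was published — the published value evidently
came from unrounded per-trial data, and `fixture_check()` reports this one
comparison as failing rather than papering over it. The published head→eye
column mean (3.8 × 10⁻²) likewise disagrees with the recomputed mean of the
packaged column (4.51 × 10⁻²); the package always reports recomputed values.

Because the cohort's raw rotation series were processed with an unstated
probability estimator and discretization, per-trial TE values are *not*
exactly reproducible from raw data by any fixed choice of B and scheme; the
packaged tables are therefore the ground truth for downstream statistics,
and the estimator is validated independently against analytic limits and a
brute-force oracle.

## Test problem sizes

The test suite validates the estimator at three scales, chosen as the
smallest sizes at which each property is sharp: exact oracle equality on
≤50-sample, ≤6-symbol instances; the 1-bit copy-process limit at $10^5$
samples (±0.01); and stochastic calibration at the reference trial length —
50 independent-pair runs at $n = 16{,}200$, B = 8 for the false-alarm rate
of the 6-Sigma rule (≤10%), and 50 seeded strong-coupling runs
(`gaussian_ar`, coupling 0.8, noise 0.2) for detection rate and NUID sign
(≥90%). Power sweeps in the module tests use shorter series (n = 4,000) and
fewer seeds, which is sufficient to establish monotonicity of detection in
coupling strength.

## Known limitations

* Plug-in TE on 8-bin histograms is biased upward on short series; the
  surrogate machinery corrects the comparison, not the raw TE value — raw
  TEs should not be compared across trials of very different lengths.
* The shuffle null destroys *all* autocorrelation; for history lengths
  beyond 1, block or stationary-bootstrap surrogates would be the
  appropriate null and are not implemented.
* `coord_amount()` is direction-blind by construction; it complements, never
  replaces, UID/NUID.
* Yaw wrap-around (±180°) is not unwrapped by default — driving yaw stays
  far from the discontinuity; recordings that cross it should be loaded with
  `unwrapped = TRUE` after continuity correction.
* The significance level λ is a scaled deviation, not a p-value; Chebyshev
  confidence is a lower bound, and λ values are comparable across trials
  only qualitatively.
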