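# coordte

Directional head–eye coordination from transfer entropy.

During goal-directed sensorimotor tasks such as driving, the head and the
eyes cooperate in two recognizable patterns: a *preparatory* pattern in which
head motion leads the gaze shift, and a *reactive* one in which the eyes move
first. `coordte` quantifies which pattern dominates in a pair of rotation
time series (eye yaw `X_t`, head yaw `Y_t`, degrees, fixed sampling rate) and
links that quantity to task performance. It is written for researchers
analyzing head-worn eye-tracking recordings (VR driving simulators, natural
locomotion studies) who want a model-free, direction-resolved coordination
measure rather than event-based fixation statistics.

## The measures

The series are discretized into `B` histogram symbols and directed
information flow is estimated with plug-in **transfer entropy** (history
length 1 in both channels, log base 2):

```
TE(Y→X) = H(X_t | X_{t−1}) − H(X_t | X_{t−1}, Y_{t−1})
```

From the two directions the package derives:

- **UID** = `TE(Y→X) − TE(X→Y)` — the unidirectional information
  difference. Positive: head leads eye; negative: eye leads head.
- **λ** — a significance level for UID against an ensemble of
  randomly-shuffled surrogate pairs: `λ = (UID − μ_S) / σ_S`. By Chebyshev's
  inequality `λ > 6` (the 6-Sigma rule, 71 surrogates) rejects the
  no-coupling null with distribution-free confidence above 97.2%; `λ > 4.47`
  corresponds to the 95% practical floor.
- **NUID** = `NTE(Y→X) − NTE(X→Y)`, where
  `NTE = (TE − μ_shuffled-source) / H(X_t | X_{t−1})` is the
  surrogate-bias-corrected transfer entropy normalized by its entropy
  ceiling. NUID places both directions on a common dimensionless scale; it is
  the quantity that correlates with driving performance.
- **CoordAmount** = `10·log10(360² / mean((y_t − x_t)²))` dB — a PSNR-style
  magnitude-match score that attests coordination exists but carries no
  direction.
- **Driving performance** = `1/AvgAcc` (s²/m), the inverse mean absolute
  acceleration of the speed trace — larger is smoother speed-keeping.

Cohort-level helpers run the two-direction ANOVA and the
Pearson/Kendall/Spearman correlation report between NUID and performance.

## Worked example

Simulate a 3-minute head-leads-eye recording (16,200 samples at 90 Hz, the
package's reference trial length) and run the pipeline:

```r
library(coordte)

spec <- coupling_spec("headeye_like", n = 16200, coupling = 0.8,
                      noise_sd = 1, seed = 42)
rec  <- simulate_pair(spec)
pair <- select_axis(rec, "yaw")
eye  <- discretize(pair$eye, 8)
head <- discretize(pair$head, 8)
cfg  <- significance_config(seed = 1)   # chebyshev_k = 6, 71 surrogates

uid <- compute_uid(transfer_entropy(head, eye), transfer_entropy(eye, head))
uid
#> <uid_result> TE head->eye 0.0776888, TE eye->head 0.0121717, UID 0.0655171 bits

significance(uid$uid, uid_surrogate_ensemble(eye, head, cfg), cfg)
#> <significance_result> observed 0.0655171 vs null (mu 7.96689e-05, sigma 0.00175595): lambda = 37.27 -> significant

compute_nuid(eye, head, cfg)
#> <nuid_result> NTE head->eye 0.0919738, NTE eye->head 0.0128632, NUID 0.0791106

coord_amount(pair$eye, pair$head)
#> <coord_amount_result> 23.55 dB (mean squared difference 572.556 deg^2 over 16200 samples)
```

Reading: 0.066 bits flow from head to eye beyond what the eye's own past
explains, 37 ensemble standard deviations above the shuffled null — the
simulated head-leads-eye coupling is detected, and the positive NUID (0.079)
gives its normalized strength. The dB score confirms the two traces co-vary
in magnitude but says nothing about direction.

For recordings on disk, `analyze_trials(files, run_config(...), output_dir)`
runs this per trial and writes the metrics table plus cohort report;
`inst/cli/coordte.R` exposes the same as a command line.

## Packaged reference cohort

`cohort_te()`, `cohort_uid()` and `cohort_nuid()` return the per-trial
results of a 12-participant × 4-trial VR driving study (3-minute sessions,
40 km/h speed-keeping task, 90 Hz head-worn tracking), on the conventional
×10⁻² printing scale. `fixture_check()` recomputes the cohort's headline
statistics from these tables and reports each against its published value.

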