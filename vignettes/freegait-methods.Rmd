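---
title: "Methods: gait speed estimation, walking bouts and medication states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait speed estimation, walking bouts and medication states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`freegait` compares gait speed measured under supervision (laboratory
walking tests) with gait speed measured unsupervised over a full day at
home, separately for medication ON and not-ON periods in people with
Parkinson's disease. This vignette is the package's account of the
science: the estimator, the segmentation and state rules, the
statistical layer, the synthetic-data model that stands in for patient
recordings, and the design decisions taken where a published protocol
leaves the details open.

## 1. Per-stride speed from a foot-worn IMU

A single 6-axis IMU on the foot (accelerometer in m/s², gyroscope in
rad/s; 100 Hz supervised, 128 Hz unsupervised — the algorithms are
parameterized by sampling rate, nothing is resampled) observes a
signal with a convenient structure: once per gait cycle the foot is
flat and motionless. Those still periods anchor the whole estimate.

**Still detection.** A sample is "still" when the gyroscope magnitude
is below `gyro_thresh` (default 0.8 rad/s) *and* the accelerometer
magnitude is within `accel_band` (default 0.8 m/s²) of gravity
(9.81 m/s²). False gaps of up to 2 samples are closed morphologically,
and still runs shorter than `min_still` (default 0.08 s) are discarded.
The composite test matters: the gyroscope rate crosses zero twice
mid-swing, but at those instants the linear acceleration is far from
gravity, so the conjunction rejects them.

**Strapdown integration with zero-velocity updates.** For each movement
interval between consecutive still intervals:

1. initialize orientation from the mean accelerometer vector over the
   tail (up to 0.5 s) of the preceding still interval — the shortest
   rotation mapping the measured gravity direction onto vertical. Yaw is
   unobservable without a magnetometer and irrelevant: speed is a
   displacement *norm*.
2. propagate orientation by quaternion integration of the gyroscope
   (trapezoidal angular increments);
3. rotate the specific force into the navigation frame and subtract
   gravity;
4. integrate to velocity (trapezoid);
5. remove drift by subtracting the linear ramp that makes velocity
   exactly zero at both bounding still samples (the zero-velocity
   update). Linear de-drifting is adopted deliberately: over one gait
   cycle, the dominant error sources (constant attitude error, slowly
   varying gyro bias) produce near-linear velocity drift, and the ramp
   removes it exactly by construction;
6. integrate velocity to displacement; the stride speed is the 3-D
   displacement norm divided by the gait-cycle duration.

**Gait cycle convention.** One stride runs from foot-flat onset to the
next foot-flat onset. With one speed per cycle of the instrumented
foot, uniform cadence gives duration exactly one cycle even when cycle
times vary. After a long standing rest the preceding "foot-flat" is
mostly standing, so its contribution to the cycle is capped at
`max_flat` (default 0.8 s, about twice a typical foot-flat) and the
stride is flagged `after_rest`; flagged strides are retained in bout
segmentation but their speeds carry that quality flag. Movement
intervals longer than `max_stride_duration` (default 4 s) cannot be a
single gait cycle and produce no stride.

**Lab trials.** For supervised tests, the first two and last two gait
cycles are trimmed (gait initiation and termination) and the remaining
speeds averaged. Fewer than five detected strides leaves nothing
meaningful after trimming; the result is flagged
`insufficient_steady_state_strides`. Turning strides in the circular
task are *not* filtered out — turning is that task's purpose — so its
speed is chord-based (displacement norm over the cycle), which is
systematically a few percent below path speed on a tight circle.

Accuracy on synthetic recordings under the default noise model
(accelerometer σ = 0.05 m/s², gyroscope σ = 0.01 rad/s, bias
0.005 rad/s — consumer-MEMS magnitudes) is computed by the test suite
and the acceptance script, not quoted here; the design goal is a mean
absolute per-stride error within the validated accuracy of published
foot-worn ZUPT estimators (≈ 3 cm/s).

## 2. Walking bouts and medication states

**Bouts.** Free-living strides are grouped into walking bouts: maximal
runs with inter-stride gaps ≤ `max_gap_s` (default 3 s, the
conventional free-living break threshold; configurable). Bout duration
is first stride start to last stride end. Classes: excluded (&lt; 15 s,
kept in the raw table but out of all analyses), short (15–30 s), medium
(&gt; 30–60 s), long (&gt; 60 s). The 30 s tie goes to short because the
medium class is open on the left; 15.0 s is included, 60.0 s is medium.

**Slow-stride filter.** Gait cycles below `min_speed_ms` (default
0.2 m/s) are treated as static shuffling and removed from every speed
summary — but only from summaries: segmentation sees the full
sequence, so a slow stride does not split a bout. The rule applies to
home data; lab trials use the trim rule instead.

**States.** Each diary intake defines a not-ON window from 30 min
before to 30 min after intake, and an ON window 60–180 min after
intake. Windows are unioned per state across doses. When doses are
closer than 210 min an ON window collides with the next dose's not-ON
window; the default policy is `noton_wins` (being near an intake means
the drug effect is not established). `on_wins` and `drop` are available
in the configuration. All other time is unlabeled — in particular,
end-of-dose time beyond 180 min is *not* called OFF, it is simply not
classified. A bout's (or stride's) state is the label at its midpoint;
intervals are closed on the left, open on the right, so a midpoint
exactly 60 min after intake is ON. Midpoint assignment is
deterministic and order-free; both bout-level and stride-level labels
are emitted because the distribution summaries use strides while the
bout statistics use bouts.

The diary and sensor clocks are not synchronized by any protocol step;
`io$diary_offset_s` exposes the offset explicitly (default 0, i.e. the
diary is assumed to be on the recording's time base).

## 3. Speed summaries and the statistical layer

Per subject and state: the 25th, 50th, 75th, 90th percentiles and the
maximum of all retained stride speeds (percentile approach), and the
25th, 50th percentile and maximum of per-bout mean speeds within each
bout class (bout approach). Percentiles use linear interpolation
between closest ranks (R's type 7) — fixed and documented so results
are reproducible; empty cells are flagged rather than imputed.

Group-level comparisons are normality-gated at α = 0.05 with
Shapiro–Wilk:

* **Paired comparisons** (lab vs home; ON vs OFF): the gate is applied
  to the paired *differences* — that is what the paired *t*-test
  assumes — selecting paired *t* or the Wilcoxon signed-rank test.
  All-zero differences are reported as degenerate, not as p = 1.
* **Correlations**: Pearson if both margins pass, Spearman otherwise.
  Bands on |r|: &lt; 0.5 low, 0.5–0.7 moderate, &gt; 0.7 high (magnitude,
  because clinical-score correlations are legitimately negative).
* **R²**: a straight-line fit of the home value on the lab value;
  any variable failing normality is natural-log transformed first
  (speeds are positive; the transform is skipped with a flag if a
  variable contains non-positive values, as UPDRS items can).
  Per-variable transformation is an interpretation choice — when only
  one margin is non-normal, only it is transformed.
* **Multiple testing**: none by default, for comparability with the
  analysis style this pipeline reproduces; `stats$mt_correction: BH`
  adds Benjamini–Hochberg columns without changing the raw ones.
* The grid's "comparison p" column tests the lab value against the
  home value per subject — the most natural reading of a
  comparison-plus-correlation table; this interpretation is documented
  rather than hidden.

Cells with fewer than three complete pairs are flagged
`insufficient_n`. Fast-pace trials in the OFF state are excluded from
the cohort grid (very few fluctuating patients can perform them) while
remaining legal in the schema, flagged at ingest.

## 4. The synthetic-data model

No patient recordings ship with the package; every claim is tested on
synthetic data with exact ground truth.

**Signal level.** A stride is foot-flat followed by swing. During
swing, path speed follows a raised-cosine bump `v(u) ∝ 1 − cos 2πu`
(zero at both ends, closed-form integral equal to the stride length),
foot clearance follows `sin²(πu)`, pitch follows a smooth excursion
with zero angle *and* zero rate at both ends, and curved walking adds a
smooth heading ramp. All channels are differentiated analytically;
ideal gyroscope rates and specific forces are emitted exactly, then
Gaussian noise and a constant gyro-bias vector are added. Straight
strides have closed-form truth displacement; curved strides integrate
the analytic velocity at 51× oversampling (quadrature error ~1 nm).
Self-consistency — double integration of the noiseless signals
reproduces the specified displacement to 10⁻³ m — is asserted in the
test suite. Trapezoidal integration at 128 Hz is accurate to ~0.03 cm/s
on these profiles, an order of magnitude below the noise-driven error.

**Day level.** A 12-h day with three doses (09:30, 13:30, 17:30 for a
9 a.m. start), Poisson bout arrivals (7/h by default in every state —
bout *frequency* is deliberately state-independent by default, since
the package's focus is speed, not activity volume), log-normal bout
durations (meanlog = log 20 s, sdlog = 0.8: mostly sub-30-s bouts with
a realistic long tail), and stride times ≈ 1.1 ± 0.08 s.

**Speed model and the capacity-tail linkage.** Each subject has a
latent capacity `c` (Normal(1.0, 0.15) m/s — centred on a typical PD
normal-pace speed), a medication response `d` (Normal(0.93, 0.04),
multiplying speeds when the drug effect is absent), and a behavioral
factor `exp(η)`, η ~ Normal(0, 0.15): how fast people *choose* to walk
at home is not fully determined by what they *can* do. Habitual bouts
run at `0.83·c·exp(η)` (ON) or `0.77·c·d·exp(η)` (not-ON) — the 0.83
and 0.77 multipliers place home medians below lab normal-pace speed,
as free-living gait consistently is. Two tail mechanisms tie the
distribution extremes to capacity: 15% of ON bouts are purposeful
brisk walks near `1.45·c`, and 30% of not-ON bouts sit at the
impairment floor `0.55·c·d`. Consequently the home *maximum* during ON
is an expression of capacity (like a supervised fast-pace test), while
the home 25th percentile during not-ON expresses the impairment floor
(like a supervised OFF test) — the qualitative signature the cohort
grid is designed to detect, encoded as a generative mechanism rather
than asserted post hoc. Lab means share the same latents:
`fast = 1.25·c`, `normal = 1.0·c`, `circular = 0.7·c`, times `d` in
OFF, plus trial noise (σ = 0.03 m/s, + 0.04 for the circular task).

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: tremor and dyskinesia artifacts in
the raw signals, freezing of gait, heel-strike impact transients,
slopes and stairs, sensor mounting play, magnetometer effects, diary
errors (wrong or missing intake times), and any within-day drift of
the medication response. Estimator accuracy on real PD gait must come
from validation studies against instrumented walkways; the synthetic
results establish correctness of the implementation, not clinical
accuracy.

## 5. Numerical and testing choices

* Trapezoidal integration throughout (velocity, displacement, angular
  increments); quaternion renormalization is unnecessary over
  single-cycle horizons.
* Degenerate inputs are flagged, never silently dropped: empty states,
  all-slow stride sets, constant variables, all-zero paired
  differences, cohorts smaller than three.
* Tie-breaks are fixed and tested: 30 s bouts are short, 0.2 m/s
  strides are kept, window edges are closed-left/open-right, band
  breakpoints sit exactly at 0.5 and 0.7.
* Problem sizes in the test suite are chosen for a desk-scale run:
  500-stride accuracy batches, 1000-replicate type-I calibration at
  n = 27, 120-replicate null calibration of the day pipeline, and 200
  simulated cohorts for the correlation-ordering check; each is stated
  in the corresponding test.
* All generators are deterministic under a fixed seed; truth tables
  always accompany generated data.

## 6. Known limitations

* Linear de-drifting cannot represent curvature in the velocity drift
  within a cycle (e.g. strong bias instability); orientation-error
  feedback filters could, at the cost of more states and tuning.
* The first gait cycle after a standing rest has no well-defined cycle
  duration; the `max_flat` cap is a convention, and `after_rest`
  strides should be excluded from tight per-stride analyses.
* Stride detection presumes foot-flat actually occurs; severely
  shuffling gait without still periods defeats any ZUPT method.
* The state windows are definitions, not measurements — time outside
  them is unlabeled, and no pharmacokinetic individualization is
  attempted.
* With 100 Hz input the estimator simply integrates at 100 Hz; no
  claims are made about rates below ~50 Hz, where foot-flat windows
  shrink below `min_still` resolution.
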