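# freegait

Gait speed from foot-worn inertial sensors, in the lab and in daily life.

`freegait` is an R package for researchers studying motor fluctuations in
Parkinson's disease (and free-living gait more generally) with body-worn
inertial measurement units (IMUs). It implements a complete analysis
pipeline:

1. **Per-stride gait speed** from a single foot-mounted 6-axis IMU, by
   strapdown inertial integration with zero-velocity updates (ZUPT):
   orientation is initialized from the gravity direction during foot-flat,
   the gyroscope is quaternion-integrated to track orientation, the
   rotated, gravity-free acceleration is integrated to velocity, the
   residual drift is removed by forcing zero velocity at both bounding
   foot-flats, and speed is `‖∫v dt‖ / T` over one gait cycle (foot-flat
   onset to next foot-flat onset).
2. **Walking bouts and medication states** for free-living days: maximal
   stride runs with gaps ≤ 3 s become bouts, classed by duration
   (excluded &lt; 15 s, short 15–30 s, medium &gt; 30–60 s, long &gt; 60 s);
   strides slower than 0.2 m/s are dropped from speed summaries; a dosing
   diary defines ON (60–180 min after intake) and not-ON (±30 min around
   intake) windows, and each bout/stride takes the state at its midpoint.
3. **Supervised-vs-unsupervised statistics**: per-subject speed
   percentiles (25/50/75/90/max) and per-bout-class statistics (25/50/max
   of bout means), compared across subjects against supervised lab tests
   (20-m straight walk at normal and fast pace, circular walk) with
   Shapiro–Wilk-gated paired tests (paired *t* / Wilcoxon signed-rank) and
   correlations (Pearson / Spearman), correlation bands (|r| &lt; 0.5 low,
   0.5–0.7 moderate, &gt; 0.7 high), and R² from a straight-line fit with
   log transform of non-normal variables.
4. **Synthetic data with exact ground truth**: closed-form foot
   trajectories (zero velocity and level orientation at both foot-flats)
   differentiated analytically into ideal gyro/accelerometer signals plus
   configurable MEMS noise, so the estimator can be validated against
   analytically known stride speeds; plus simulated 12-hour patient days
   and full cohorts whose lab and home speeds share a latent gait
   capacity per subject.

## Worked example

Estimate steady-state speed of a supervised 20-m walk (synthetic here;
with real data, start from `read_imu()`):

```r
library(freegait)
set.seed(11)
specs <- lapply(1:18, function(i) stride_spec(stride_length = 1.15, duration = 1.05))
walk  <- synth_walk(specs)
trial <- lab_trial(walk$rec, task = "straight_normal", med_state = "ON")
process_lab_trial(trial)
#> <trial_speed_result> straight_normal/ON: 18 strides, 4 trimmed, mean 1.094 m/s
```

Eighteen gait cycles are detected; the first two and last two are trimmed
as acceleration/deceleration, and the steady-state mean (1.094 m/s)
matches the generated target of 1.15 m / 1.05 s = 1.095 m/s.

Summarize a simulated free-living day:

```r
day      <- synth_day(seed = 42)
timeline <- build_state_timeline(day$diary)
strides  <- assign_states(day$strides, timeline)
bouts    <- assign_states(segment_bouts(strides), timeline)
table(bouts$length_class)
#> excluded_short          short         medium           long
#>             32             22             15              4
summarize_subject(strides, bouts, "ON", subject_id = "S01")
#> <speed_summary> S01 @ ON: 883 strides
#>   p25   p50   p75   p90   max
#> 0.997 1.101 1.259 1.754 1.898
```

Build the full lab-vs-home comparison grid for a 27-subject synthetic
cohort:

```r
cohort <- synth_cohort(seed = 1)
home   <- cohort_home_summaries(cohort)
result <- build_cohort_grid(cohort$lab, home)
result
#> <cohort_result> 27 subjects, 140 grid cells

g <- result$grid
g[g$grid_type == "same" & g$lab_task == "straight_fast" &
    g$metric == "percentile", c("stat", "r", "band", "r2")]
#>  stat    r     band   r2
#>   p25 0.52 moderate 0.27
#>   p50 0.52 moderate 0.27
#>   p75 0.52 moderate 0.33
#>   p90 0.61 moderate 0.37
#>   max 0.98     high 0.95
```

During ON, the supervised fast-pace test correlates most strongly with
the *fast tail* of home walking (r climbs from 0.52 at the 25th
percentile to 0.98 at the maximum), because purposeful brisk walking at
home expresses the same capacity the fast test measures. During
OFF/not-ON the pattern reverses: lab speeds correlate best with the 25th
percentile (slow tail), where the impairment floor dominates.
`write_report()` saves the grid as JSON + CSV.

A command-line front end with `estimate`, `analyze`, `simulate` and
`pipeline` subcommands is installed at `inst/cli/freegait.R`; every
configuration key (YAML, see `default_config()`) can be overridden via
`--config`.

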