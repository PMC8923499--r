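# rheotrack

Estimating how juvenile fish actually swim — not just where they go — from
fine-scale acoustic telemetry in a flowing river.

A tag on a migrating smolt reports positions; the river moves too. The
swimming behavior is the difference: with a track giving velocity over
ground **u**og and a hydrodynamic field giving the water velocity
**u**h at the fish's location, the swim velocity is

```
u_s = u_og − u_h
```

rotated into the local flow frame as a longitudinal component `u_long`
(positive downstream, so negative values mean positive rheotaxis —
swimming against the current) and a lateral component `v_lat` (positive
toward river right). Getting there requires solving several upstream
problems that `rheotrack` implements as composable, tested stages:

- **Clock synchronization** (`solve_sync()`): receiver clocks drift by
  large fractions of a second while time-of-flight signals are worth
  tenths of milliseconds. With hydrophone positions fixed, the
  synchronization problem reduces to sparse linear least squares over
  per-ping emission times and continuous piecewise-linear clock-offset
  functions; erroneous detections are removed one worst residual at a
  time until the RMS residual drops below 1 ms.
- **Multipath dedupe and multilateration** (`dedupe_multipath()`,
  `assemble_pings()`, `locate_pings()`): reflections off the bed and
  surface are discarded, detections are associated into transmission
  events, and each ping is located in 2-D by Gauss–Newton with a
  per-fix positional standard deviation.
- **Quality control** (`qc_tracks()`): the screening cascade — positional
  sd over 10 m, fewer than two receivers, endpoint truncation to
  three-receiver solutions, minimum 10 positions, 60-minute residence
  (likely predators), the analysis-region polygon with a 30 m upstream
  allowance, and a post-hoc 0.5 m/s mean-swim-speed predator rule.
- **Hydrodynamic extraction** (`extract_velocity()`, `vorticity()`,
  `local_depth()`, `calibration_metrics()`, `mean_river_velocity()`):
  vertically averaged velocities under three assumed fish depth
  distributions (top 1 m, top 2 m, full depth), central-difference
  vorticity, model-skill metrics (bias vector and unbiased RMSE with
  target-diagram coordinates), and the reach velocity `u_river = Q·L_a/V`.
- **Behavioral statistics** (`segment_weights()`, `weighted_median_ci()`,
  `weighted_kde()`, `rheotaxis_fraction()`, `stride_speeds()`,
  `ground_vs_river()`, `export_gam_table()`): per-individual inverse
  segment-count weights, bootstrapped 5–95% CIs of weighted medians,
  weighted kernel densities, stride-based noise sensitivity, the paired
  comparison of downstream movement against the mean river velocity,
  and the covariate table handed to external smooth-model fitting.
- **Synthetic data with ground truth** (`scenario_config()`,
  `gen_array()`, `gen_field()`, `simulate_fish()`,
  `simulate_detections()`, `gen_gauges()`): a 13-receiver array at
  ~70 m spacing, a sheared channel flow (log-law vertical, parabolic
  lateral profile), fish with prescribed behaviors (positive/negative
  rheotaxis, lateral swimming, passive transport), 5 s pulse-rate
  interval tags, injected clock drifts, arrival noise and
  multipath-like corrupted detections — every stage of the pipeline is
  verifiable by parameter recovery.

## Worked example

Simulate a cohort of 30 upstream-swimming fish (0.10 m/s against the
local depth-averaged flow), push it through detection simulation, clock
sync, multilateration, QC and swim-velocity estimation, and summarize:

```r
library(rheotrack)
library(dplyr)

cfg <- scenario_config(
  arrival_noise_sd = 0, detection_prob = 1, corrupt_frac = 0,
  pri_jitter_sd = 0,
  behaviors = data.frame(label = "positive_rheotaxis", fraction = 1,
                         swim_speed = 0.10, diel = FALSE))
out <- run_synthetic_pipeline(cfg, n_fish = 30, duration = 5400,
                              drift = TRUE, seed = 202)

glance(out$sync)
#> # A tibble: 1 × 5
#>   rms_residual n_iterations n_windows n_removed success
#>          <dbl>        <int>     <int>     <int> <lgl>
#> 1     6.74e-12            0         1         0 TRUE

rec <- out$records |> filter(vrange == "full", frame_defined) |>
  segment_weights()
weighted_median_ci(rec$u_long, rec$weight, n_boot = 500, seed = 7)
#> $median
#> [1] -0.1
#>
#> $ci
#> [1] -0.1 -0.1
```

The sync residual is at numerical zero because the telemetry was
simulated noise-free (the injected clock drifts themselves are recovered
exactly), and the weighted median longitudinal swim velocity recovers
the prescribed −0.10 m/s: negative `u_long` is positive rheotaxis. With
the default 0.2 ms arrival noise the sync residual settles near 0.19 ms
and positions are good to a few decimeters.

`summarize_swimming()` produces the per-vertical-range medians, CIs,
rheotaxis occurrence and weighted kernel densities in one object with
`tidy()` and `autoplot()` methods.

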