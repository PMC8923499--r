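---
title: "Methods: from drifting clocks to swim velocities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from drifting clocks to swim velocities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheotrack)
```

`rheotrack` turns raw acoustic detections of tagged fish in a river into
estimates of swimming behavior. This vignette explains the models and
procedures stage by stage, the assumptions behind them, the parameters
that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer would want written down.

## Coordinate frame and conventions

All modules share a local planar Cartesian frame in meters: `x`
along-channel, positive downstream; `y` cross-channel; `z` positive up
with the undisturbed surface near 0; time in seconds. The flow frame at
a point is defined by the downstream unit vector `f` of the
depth-averaged hydrodynamic velocity. A swim vector is decomposed as
`u_long = u_s · f` (positive downstream, so negative values indicate
positive rheotaxis) and `v_lat = u_s · (f_y, −f_x)` (positive toward
river right, the right of an observer facing downstream). With flow
along `+x` this makes river right the `−y` direction; the synthetic
lateral-swimming policy swims along `(f_y, −f_x)`, so prescribed and
recovered lateral velocities share one sign convention end to end.

## Clock synchronization by sparse least squares

Submersed receivers drift by O(0.1–1 s) between resynchronizations
while time-of-flight differences worth resolving are O(0.1 ms). With
receiver positions surveyed and held fixed, synchronization is a linear
problem. Each beacon detection contributes one equation

$$ t^{raw}_{hk} - d_{hk}/c \;=\; T_k + \textstyle\sum_j w_j(t)\,\theta_{hj}, $$

where \(T_k\) is the unknown emission time of ping \(k\), \(d_{hk}\)
the known source–receiver distance, \(c\) the sound speed, and
\(\theta_{hj}\) the knot values of receiver \(h\)'s continuous
piecewise-linear clock-offset function (hat-function weights
\(w_j(t)\)). One reference receiver — in practice a cabled,
network-resynchronized unit — has its offset pinned to zero; this fixes
the gauge freedom (adding a constant to all offsets and emission times
changes nothing observable).

The solver eliminates the emission times analytically: within each ping,
subtracting the group mean of both sides removes \(T_k\) (the Schur
complement of the block-diagonal emission-time block), leaving a small
sparse normal system in the \(\theta\) alone. This is algebraically the
same least-squares solution as the full system, at a fraction of the
cost, and it is what lets the removal loop re-solve hundreds of times
cheaply.

Erroneous detections are handled by a two-layer defense mirroring how
multipath actually enters the data:

1. **Dedupe pre-pass.** Repeat receptions of one ping on one receiver
   within a short window (default 1 s) are reflections off the bed or
   surface; all but the earliest are dropped before the solve.
2. **Worst-residual removal.** While the RMS residual of retained
   detections exceeds `rms_threshold` (default 1 ms), the single
   detection with the largest absolute residual is removed and the
   system re-solved. Removal of the worst residual can be shown never to
   increase the RMS, so the loop terminates; a cap
   (`max(0.5% of detections, 100)`) guarantees termination even on
   pathological input, in which case the window is flagged
   unsuccessful.

Removal granularity is a single receive record, not a whole
transmission: multipath corrupts individual receiver–ping pairs.

**Knot placement.** Interior knots sit on the absolute `knot_interval`
grid (default 1 h); the two end knots are snapped to the first and last
detection of the window. The end knots therefore always carry the
extreme detections at full hat weight and stay well conditioned, and
interior knots align across windows. Where a particular receiver has no
detections supporting a knot, that knot is unidentifiable for that
receiver; it is filled by flat extension from the nearest supported
knot and flagged `supported = FALSE`. Long records are solved in
independent windows (default 5 days) to balance continuity against
cost. Higher-order offset interpolants are deliberately not offered.

## Multilateration

Positions are estimated per ping: detections of one tag are clustered
into transmission events (two detections join a group when their
corrected times differ by less than the array's maximum propagation
delay), and each group with at least three distinct receivers is solved
by Gauss–Newton for \((x, y, T)\) minimizing
\(\sum_h (t_h - T - d_h(x,y)/c)^2\). The water column is too shallow
for vertical resolution, so the tag depth is fixed (default 1 m below
the surface) and enters only through the slant ranges. The reported
`sd` is the square root of the mean diagonal of the linearized position
covariance scaled by the residual variance — a per-axis uncertainty
scale. Two-receiver groups are counted but not located: recovering them
requires a whole-track motion prior, which this per-ping solver
deliberately omits in favor of transparency and testability; the
downstream QC rule "fewer than two receivers" remains expressible.
Initialization uses the tag's previous fix when less than 60 s old,
else the array centroid; non-convergence within 50 iterations or a
solution more than 1 km from the array rejects the fix.

## Quality control

The screening cascade runs in a fixed order — fix-level filters,
endpoint truncation, region clip, track-level rules — because the rules
do not commute:

1. fixes with positional `sd > 10` m (strictly) or fewer than 2
   receivers are eliminated;
2. tracks are truncated to start and end with fixes using at least 3
   receivers (interior 2-receiver fixes are retained);
3. fixes are clipped to the analysis-region polygon, with an allowance
   of up to 30 m upstream of the region's upstream (−x) edge;
4. tracks with fewer than 10 remaining positions are omitted; tracks
   resident in the region longer than 60 min are flagged as likely
   predators and omitted (the residence clock runs over in-region
   fixes, since the bound derives from expected transit time through
   the array);
5. once swim records exist, tags with mean swim speed above 0.5 m/s
   (strictly) are eliminated as likely predators.

Every rejection is logged with a rule name, so the kept set plus the
log partitions the input; the cascade is idempotent.

## Hydrodynamic extraction

The `flow_field` container holds `u, v` on a rectilinear
\((x, y, z, t)\) grid with bed and free surface. Because the fish's
vertical position is unobserved, velocities are referenced to three
assumed vertical distributions: uniform over the top 1 m, the top 2 m,
or the full water column. Slabs are measured down from the
*instantaneous* free surface — "top 1 m of the water column" in a tidal
channel is a moving window — and clipped to the available depth.
Extraction interpolates linearly in \(x, y, t\) and averages the
vertical profile by the trapezoid rule with interpolated slab
endpoints.

Vorticity \(\omega_{xy} = \partial v/\partial x - \partial u/\partial y\)
(the lateral shear) is computed by central differences of the
interpolated, vertically averaged field with stencil half-width `h`
(default 2 m, the lateral grid scale of channel-resolving models). All
four stencil points must be wet; there is no one-sided fallback, so a
rejection is explicit rather than silently biased.

Model skill against observed velocities uses the bias vector
\(b = \langle m_i - o_i\rangle\) and the unbiased RMSE
\(\sqrt{\langle\|m_i - o_i - b\|^2\rangle}\), which satisfy the exact
decomposition \(\langle\|m_i-o_i\|^2\rangle = uRMSE^2 + \|b\|^2\) (a
test invariant). Target-diagram coordinates put longitudinal bias on
the ordinate and uRMSE on the abscissa, signed by whether the model
over- or under-predicts the standard deviation of the observed *vector
magnitudes*; signing by total rather than longitudinal variance is a
convention choice this package fixes in its contract.

The mean river velocity is \(u_{river}(t) = Q(t)\,L_a / V(stage(t))\)
with characteristic flow-path length `La` (default 234 m) and a
monotone stage-to-volume curve supplied as a table (deriving it from a
DEM is out of scope).

## Swim velocity and covariates

Successive fixes of one tag form a segment; `u_og` is the vector
displacement over the elapsed time, and the hydrodynamic velocity is
extracted at the segment's spatial and temporal midpoint. Segments
longer than `max_gap` (default 20 s = 4 pulse-rate intervals) are not
formed: interpolating across missed pings would smear velocities. The
swim velocity is the vector difference, rotated into the flow frame
using the *full-depth* flow direction for all three vertical ranges, so
the three ranges differ only in the reference speed, not orientation.
Near slack water (depth-averaged speed below 1 mm/s) the frame is
undefined; records keep their vector components but are flagged and
excluded from flow-frame statistics rather than assigned an arbitrary
axis.

Covariates filled at each midpoint: hydrodynamic speed and vorticity
for the record's own vertical range, local depth, local time of day,
mean river velocity, and turbidity joined by nearest gauge time within
30 min.

## Weights, summaries, and sensitivity analyses

A fish that swims downstream transits the array quickly and leaves few
segments; an upstream swimmer leaves many. Unweighted pooling would
overweight upstream behavior, so records are weighted by the inverse of
the individual's segment count, equalizing each fish's total weight.
When the three vertical ranges are pooled as replicate measurements, an
additional factor of 1/3 avoids inflating the degrees of freedom.

The weighted median is the smallest value whose cumulative normalized
weight reaches 0.5; its 5–95% CI comes from bootstrap resampling with
selection probability proportional to weight (default 1000 resamples,
explicit seed). The weighted kernel density uses a Gaussian kernel on a
grid spanning the data ±3 bandwidths, with Silverman's rule applied to
the weighted standard deviation and the effective sample size
\((\sum w)^2/\sum w^2\); equal weights reduce both estimators exactly
to their unweighted forms.

Speeds (unlike velocity components) are biased upward by uncorrelated
positional noise. `stride_speeds()` quantifies this by recomputing swim
speeds over fix pairs \((i, i+k)\): the noise contribution to each
velocity falls as the interval grows, so the median speed declines with
stride, and the stride-1 minus long-stride difference bounds the
combined effect of telemetry noise and path sinuosity.

`ground_vs_river()` asks whether behavior made fish faster or slower
than the water overall: each fish's downstream velocity over ground
(net in-region x-displacement over elapsed time) is paired with the
time-averaged mean river velocity over the same interval and tested by
a two-sided paired t-test (closed-form statistic, `pt()` p-value, 90%
CI by default). Zero variance of the differences is reported as a
degenerate case rather than an error.

`classify_behavior()` labels tracks from median flow-frame components
with declared heuristic thresholds (0.05 m/s by default); these are
package conventions, not field-derived constants.
`export_gam_table()` emits one weighted row per (segment, vertical
range) with all covariates; smooth-model fitting (e.g. `mgcv::bam` with
an AR(1) term) is intentionally external to this package.

## The synthetic generator: what it emulates, and what it does not

`scenario_config()` defaults encode the study conditions the pipeline
targets: 13 receivers nominally 70 m apart on a staggered grid along a
1000 m × 50 m × 4 m channel, 5 s tag pulse-rate interval with 0.1 s
Gaussian ping jitter, beacons every 30 s, sound speed 1470 m/s (fresh
water at 15–20 °C; the value is configurable), piecewise-linear clock
drifts up to 0.5 s with knots every 6 h, and 0.1% of detections
corrupted by a 5–50 ms multipath-like delay. The arrival-noise sd
defaults to 0.2 ms — chosen so that the 1 ms RMS stopping rule is
meaningful (clean data converge well below it; corrupted data sit above
it), since no field value was available to copy.

The corruption surrogate *duplicates* the affected detection and delays
the copy, reproducing the late-reflection pattern that the dedupe rule
targets; an in-place mode (`corrupt_mode = "delay"`) exists for
stress-testing the solver's removal loop directly. The flow field is
separable — log-law vertical profile over roughness \(z_0\) (the 1/30
physical-roughness scaling convention), parabolic lateral profile
vanishing at the banks, optional sinusoidal tidal modulation — and fish
integrate \(dx = (u_h + u_{swim})\,dt\) with Euler steps of
`dt = 0.5 s`, well below the ping interval so the integration error
(O(dt) in the velocity recovered from 5 s segments) stays under
0.005 m/s, below telemetry noise scale. Behavior policies: swim
against, with, or perpendicular to the local depth-averaged flow, or
not at all; in slack water fish keep their last flow-derived heading
rather than freezing, so lateral swimmers beach and their tracks
truncate instead of lingering artificially past the residence limit.

What the generator does **not** emulate — and therefore what passing
recovery tests do and do not show: no junction or route-selection
geometry (a single channel suffices for recovery), no
detection-efficiency dependence on range or noise bursts, no vertical
fish movement (the pipeline's vertical-range spread is exactly the
uncertainty proxy for that), no correlated telemetry errors (stride
analyses on real data bound, not measure, that correlation), and no
hydrodynamic model error — recovery tests validate the pipeline's
algebra and estimation machinery, not the fidelity of any real river's
flow field.

## Numerical choices and degenerate inputs

- Interpolation outside the grid or in dry cells is a rejection (or
  `NA` under `strict = FALSE`); no extrapolation anywhere.
- The sync solver drops normal-equation columns with diagonal below
  1e-10 (no support) and falls back to a tiny ridge (1e-8) only on
  exact rank deficiency after removals, reporting affected receivers.
- Gauss–Newton convergence is a position step below 1e-6 m; distances
  are floored at 1e-6 m to avoid singular Jacobians at a receiver.
- Weighted-median ties resolve to the smallest qualifying value by
  definition; boundary QC rules are strict inequalities ("exceeds
  10 m", "above 0.5 m/s"), so values exactly at a threshold survive.
- Bootstrap and KDE require at least 100 resamples and 2 distinct
  values respectively; all-equal bootstrap input yields a zero-width
  CI, which is a valid answer, not an error.
- Problem sizes in the test-suite simulations (one simulated day of
  beacons for synchronization; cohorts of 30 fish over 90 minutes for
  recovery) were chosen as the smallest scales at which each stage's
  statistical behavior is cleanly visible.

## Known limitations

- The per-ping position solver cannot use 2-receiver detections and
  carries no motion prior; positional uncertainty is therefore larger
  than a whole-track maximum-likelihood smoother would report, and the
  reported `sd` is a per-axis scale (coverage of the 2-D error norm at
  2·sd is ~0.82–0.86, not the ~0.95 of a 1-D reading).
- Clock-offset functions are piecewise linear between knots; abrupt
  clock steps inside a knot interval are absorbed as residuals until
  the removal loop or a shorter `knot_interval` handles them.
- The field serialization is a portable text format (JSON header + CSV
  arrays) meant for interchange and fixtures, not for very large
  gridded model output.
- `u_river` uses a supplied stage-to-volume table; no bathymetric
  integration is performed.
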