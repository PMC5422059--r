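---
title: "Methods: inertial movement detection, calibrated dead reckoning and frame quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inertial movement detection, calibrated dead reckoning and frame quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(branchnav)
```

branchnav re-implements, at desk scale, a smartphone sensor-fusion workflow
for monitoring densely planted coffee: **navigation mode** (NM)
georeferences individual trees from GPS-seeded inertial dead reckoning, and
**acquisition-control mode** (ACM) detects the start and end of the slow
translation of a handset along a fruit-bearing branch so that the companion
video can be trimmed to its useful part and its sharpest frames selected.
This vignette describes the models, the tunable constants, what the
synthetic generators do and do not emulate, and the numerical choices made
where the design was open.

## 1. Static/movement segmentation

Both modes rest on the same detector. For an inertial channel $is$ (the
horizontal linear accelerations $AccL_x, AccL_y$ in NM; the angular
velocity $\omega_y$ in ACM, all sampled at 100 Hz) the magnitude
$\mathrm{Mag}_{is}(t) = \sqrt{is(t)^2}$ is reduced to a block-wise
local-maxima envelope: the series is cut into consecutive windows of $M$
samples and every sample in a window is replaced by the window maximum.
A sample is *moving* when the envelope exceeds the dynamic threshold

$$\mathrm{THD}_{is} = \mu(\mathrm{Mag}_{is}) + K\,\sigma(\mathrm{Mag}_{is}),$$

floored at a per-channel minimum `min_thd`, the largest magnitude observed
while an operator merely holds the device. Defaults (window $M = 85$
samples, $K$ = 1.8 / 0.44 / 1.8 and floors 0.15 / 0.15 / 0.05 m s^-2^ or
rad s^-1^ for acc_x / acc_y / gyro_y) are the published operator
calibration; the threshold depends on who holds the device, so
`detection_config()` makes all of them per-site settings. Two open points
were resolved as follows:

* $\mu$ and $\sigma$ are computed over the **whole recording** (offline
  batch processing of one log per parcel or branch), not a sliding window;
  per-operator adaptation is a config swap.
* In NM the two acceleration channels are combined by **logical OR**:
  walking excites either horizontal axis depending on how the handset is
  carried.
* The source material names no units for the constants; this package fixes
  m s^-2^ and rad s^-1^, under which the gyroscope floor of 0.05 is a
  plausible hand-tremor ceiling.

Movement runs shorter than `min_segment` (0.3 s) are relabelled static.
Note a resolution consequence discussed in Section 6: mask runs are quantised to
whole envelope blocks, so with the default $M$ the debounce only acts on
partial tail blocks; at finer windows it suppresses single-window spikes as
intended.

```{r mask-plot}
w <- gen_walk_trace(walk_spec(step_lengths = c(1, 2.25), seed = 42))
m <- build_mask(w$trace)
autoplot(m, w$trace)
```

## 2. ZUPT, drift compensation and calibrated displacement

Within each movement segment the masked acceleration is integrated
rectangularly ($v_i = v_{i-1} + a_i\,\Delta t$, $\Delta t = 10$ ms);
velocity is pinned to zero on every static sample (the zero-velocity
update), so integration noise cannot accumulate across idle periods.
Because the device is known to be at rest when a segment ends, the residual
end-of-segment velocity is pure accumulated error. It is modelled as a
straight line from zero at the segment start to the spurious final value
$v_{end}$,

$$\hat\varepsilon(t) = m\,t, \qquad m = v_{end}/T,$$

and subtracted, which forces the compensated end velocity to zero exactly.
Compensation can drive parts of the velocity profile negative at slow
walking speed; those excursions are **not clamped** — the systematic
under-measurement they cause is removed globally by a single calibration
factor, estimated by regression through the origin of true against
estimated displacement (`fit_calibration()`; published value 1.4735 with
$R^2 = 0.98$ and a statistically zero intercept). The factor ships as a
config default and can be re-estimated from any set of (real, estimated)
pairs; `validate_calibration()` checks that the calibrated system has unit
slope on held-out movements. Rectangular rather than trapezoidal
integration is used throughout: the $O(\Delta t^2)$ difference is far below
sensor noise, and it makes the generator's discrete ground truth exact.

## 3. Georeferencing

The GPS contributes exactly one point: the seed. Its WGS84 coordinates are
projected to Gauss-Krüger plane coordinates (transverse Mercator at scale
factor 1); each movement's device-frame displacement $(\Delta X, \Delta Y)$
is rotated by the declination-corrected heading
$\theta = \mathrm{Azimuth} - DM$ (trigonometry in degrees),

$$\Delta N = \Delta Y \cos\theta + \Delta X \cos(\theta + 90^\circ), \qquad
  \Delta E = \Delta Y \sin\theta + \Delta X \sin(\theta + 90^\circ),$$

and accumulated, $N \leftarrow N + \Delta N$, $E \leftarrow E + \Delta E$.
The heading of a movement is the **circular mean** of the yaw channel over
the segment's samples (one heading per movement is required and the
aggregation was unspecified). The default `projection_spec()` is the
Colombian MAGNA-SIRGAS Bogotá zone — under which the published survey start
point inverts to a location in the central coffee region — but the zone
behind the printed coordinates is not documented, so the projection is
config-first and round-trip tests are self-consistency tests (forward ∘
inverse < 1 mm), plus an independent geodesic-distance check against
geosphere. The default declination is the published site value −6.13°.
The worst-case track error is the seed's GPS error plus the inertial
relative error (`error_budget()`).

## 4. Scan trimming and frame selection

In ACM only detection matters: below 5 cm s^-1^ the linear acceleration
cannot resolve displacement (and is not asked to — that is a stated
non-goal), but the gyroscope still sees the hand's angular motion. The
longest movement segment of the $\omega_y$ mask is the scan; its
boundaries, scaled by the frame rate and the video/log offset, give the
half-open frame range to keep (a 15 s scan at 30 fps keeps 450 frames).
Scan speeds classify as low (< 5), medium (5–10, inclusive at both ends, as
"between" is read) and high (> 10 cm s^-1^).

Frame quality is scored on the **red channel** inside three circular ROIs
(100 px diameter) at 1/4, 1/2 and 3/4 of the width on the central band,
where the branch lies:

* Sobel index: $\sum_{ROI} \sqrt{S_x^2 + S_y^2}$ (3×3 kernels);
* Laplacian index: $\sum_{ROI} |\nabla^2 I|$ (3×3 kernel);
* Canny index: sum of a 0/255 edge map over the ROI, with hysteresis limits
  $(\sigma, 3\sigma)$ where $\sigma$ is the standard deviation of the whole
  red channel — the limits adapt to scene contrast.

A frame is accepted when any ROI exceeds the operator's threshold
(1,100,000 / 54,000 / 290,000) **strictly**. The Canny sum is taken over
values encoded 0/255: under that reading the printed threshold corresponds
to ≈ 1,137 edge pixels in a ≈ 7,854-px ROI, a plausible edge density,
whereas a 0/1 encoding would demand more edge pixels than the ROI holds.
All 3×3 convolutions use replicate padding, so near-border ROIs see no
spurious frame-edge response, and a uniform image scores exactly zero.
Selection is two-stage: the beginning/middle/end frames are scored first
and if all three fail the video is flagged for re-acquisition; otherwise
all frames are scored and the accepted ones uniformly subsampled to the
retention fraction (default 0.2 — for the nominal all-sharp 450-frame scan,
90 frames). The default decision operator is the Laplacian (cheapest
kernel); the three operators discriminate velocity classes equally well, so
the choice is configuration, not science.

## 5. What the synthetic generators emulate

Nothing external ships with the package; every experiment runs on three
seeded, bitwise-reproducible generators.

**Walks** (`gen_walk_trace()`). Each step is built in *velocity* space — a
trapezoid with 20 % ramps whose plateau carries a windowed gait oscillation
(0.08 m s^-1^ at 1.3 Hz, ≈ 0.65 m s^-2^ of acceleration) — and then
differentiated. Building velocity first guarantees the physical constraint
that stopping returns velocity to zero, and makes the ground-truth step
length the exact discrete integral of the profile (the profile is
normalised so that integral equals the requested length). The gait term is
what keeps constant-velocity walking visible to an accelerometer-based
detector, exactly as human gait does. The sensor reports the true
acceleration times a sensitivity deficit of 1/1.4735 — the documented
under-measurement the calibration factor exists to undo — plus white noise
(sd = `noise_idle`/3, so idle excursions stay within the ±10 mg band) and a
constant per-trace bias within ±1 mg, which the drift line removes exactly
(it is linear in time). Defaults: step lengths from the survey grid
(0.5–3.75 m), speed 0.44 m s^-1^ (the published median, range 0.42–0.45),
idle pauses of 2 s, one GPS fix at the first sample with an error of up to
`gps_error` metres in a uniform direction.

**Scans** (`gen_scan_trace()`). $\omega_y$ is white tremor noise
(sd 0.15 rad s^-1^) for the scan duration (default 15 s, the published
average for a 50 cm branch at ≈ 3 cm s^-1^), and near-zero sensor noise
outside it, with a 2 s focusing lead-in and a 3 s trailing idle. White
tremor is deliberate: its per-block maximum (≈ 2.6 sd over 85 samples) sits
safely above the mean + 1.8 sd threshold, while narrowband (sinusoidal)
tremor of any amplitude would not — its envelope never clears
$\mu + 1.8\sigma$ when most of a recording is movement. Occasionally
(≈ 1 % of seeds) a block still dips below threshold and splits the scan;
the longest-segment rule then misses one boundary. This reproduces the
order of imperfection of the field system, which also missed 1–3 % of
starts/ends.

**Images** (`gen_branch_image()`). A red-dominant textured scene (branch
band, shaded fruit ellipses, green leaf blobs, per-pixel speckle) spanning
the central band so every default ROI contains structure; Gaussian blur
emulates defocus and a horizontal box kernel emulates motion blur. The
texture contrast is set so that the designated sharp fixture clears the
published acceptance thresholds while its σ = 8 px blurred copy clears
none — the fixtures exist to exercise the decision boundary. They are
synthetic stand-ins: no lighting variation, occlusion, or photorealistic
coffee; passing tests show the indexes and decisions behave correctly, not
that the thresholds transfer to arbitrary cameras.

## 6. Numerical choices, problem sizes and known limitations

* **Boundary resolution.** The envelope is piecewise constant on $M$-sample
  blocks, so detected segment boundaries snap to block edges: starts up to
  $M\,\Delta t$ = 0.85 s early, ends up to 0.85 s late. Displacement is
  unaffected (the widened segment integrates near-zero idle samples and the
  drift line absorbs the bias), and scan trimming errs on the side of
  keeping a few extra frames. But any evaluation that scores boundaries at
  a tolerance below 0.85 s will fail for step timings that land mid-block;
  walking steps of 0.75–3.75 m at 0.44 m s^-1^ mostly do. This is the
  method's intrinsic resolution, not an implementation artefact.
* **Mask polarity.** The stored mask is `moving = TRUE` during movement and
  multiplies the acceleration, which realises the stated effect of forcing
  signals to zero when idle (the prose encoding, zeros-for-movement, is the
  opposite of its stated effect; the effect is load-bearing).
* **Drift anchoring.** The drift line is anchored at zero at the segment
  start (integration restarts there, so the start velocity is exactly
  zero), and elapsed time is counted per integration step so the
  compensated end velocity is zero to machine precision.
* **Degenerate inputs.** Zero-duration segments, empty frame ranges,
  logs without samples, non-monotone timestamps, ROIs off the image and
  poles in the projection are errors; a constant image yields zero indexes
  (not an error), and an all-idle navigation log yields a seed-only track
  with a warning.
* **Problem sizes.** The shipped experiments use 40 movements for
  calibration (25 calibrate / 15 validate, the published 5/8 split), 200
  movements for displacement error, 200 scans for detection rates and
  Full-HD fixtures for the decision boundary; module tests use smaller
  sizes (60 trials, 480×270 fixtures). These sizes give stable statistics
  at interactive runtimes.
* **Not modelled.** Terrain slope, GPS multipath, magnetometer
  disturbance, attitude propagation (no full 3-D strapdown, no Kalman
  filter — the method deliberately uses none), and displacement measurement
  below 5 cm s^-1^, which the gyroscope-only ACM design explicitly avoids.
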