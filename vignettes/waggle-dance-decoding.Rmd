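---
title: "Detecting and decoding waggle dances: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and decoding waggle dances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beewaggle)
```

## The problem

A foraging honey bee advertises a food source by a waggle dance on the
vertical comb: during each *waggle run* she vibrates her body laterally at
roughly 13 Hz while advancing in a straight line, then circles back in a
*return run*, alternating clockwise and counter-clockwise so the path traces
a figure eight. The run's orientation relative to gravity encodes the compass
bearing of the resource relative to the solar azimuth; the run's duration
encodes its distance; the dance tempo (waggle/return duration ratio) encodes
profitability. `beewaggle` detects these runs directly in observation-hive
video, decodes orientation and duration, aggregates runs into dances, and
projects each dance onto a map around the hive.

The pipeline has four stages, run in sequence:

1. **Attention module** — per-pixel spectral change detection in the
   10–16 Hz *waggle band*, clustering of activated pixels into dancer
   positions, assembly of positions into waggle runs, and export of
   50×50 px snippet sequences.
2. **Filter network** — a compact 3D convolutional classifier that scores
   snippet sequences and flags non-waggle detections.
3. **Orientation module** — decodes each run's body orientation from the
   accumulated 2D Fourier magnitude of consecutive-frame difference images.
4. **Mapping module** — clusters runs into dances in (x, y, t), rejects
   angular outliers with RANSAC, and converts mean angle and duration to a
   field coordinate via the solar azimuth and a linear distance calibration.

## Detection model (attention module)

Each pixel keeps the last $b$ intensity values $B$. The window is min–max
normalised to $[-1, 1]$, which removes illumination gain and offset, and
projected onto sine/cosine pairs at each integer frequency
$r \in \{10, \dots, 16\}$ Hz:

$$\mathrm{score}(\bar B, r) =
  \Big(\sum_{m=1}^{b} \bar B(m)\cos\tfrac{2\pi r m}{s_r}\Big)^2 +
  \Big(\sum_{m=1}^{b} \bar B(m)\sin\tfrac{2\pi r m}{s_r}\Big)^2,$$

the periodogram ordinate at $r$. (The alternative reading that squares each
summand before the sum over $m$ is blind to phase coherence — it assigns a
pure tone and its random permutation identical scores — and is kept in the
test suite only as a documented rejected alternative.) A dot detector
activates when any band frequency scores at least $t_h$.

Key parameters, all in `attention_config()`:

| parameter | default | meaning |
|---|---|---|
| `window_len` $b$ | 32 frames | 0.32 s at 100 Hz, about 4 waggle cycles |
| `waggle_band` | 10–16 Hz | integer probe frequencies |
| `score_threshold` $t_h$ | 130 | see below |
| `cluster_dist` $d_{max1}$ | 11.9 px | half a 14 mm body at 1.7 px/mm |
| `min_cluster_size` $c_{min1}$ | 4 | smaller clusters dropped as noise |
| `link_dist` $d_{max2}$ | 12 px | max step between successive positions |
| `max_gap` $g_{max2}$ | 10 frames | run candidates survive short dropouts |
| `min_run_detections` $c_{min2}$ | 10 | minimum detections per run |
| `min_run_ms` | 200 ms | < 3 body oscillations is not a waggle |

Because of the min–max normalisation, the score of a pure-noise window
follows one fixed null distribution regardless of the noise level. That
null has a practical ceiling: scores above ~125 occur with probability
around $10^{-6}$ per window. The default $t_h = 130$ sits just above this
ceiling so that chance activations are negligible even over millions of
pixel windows, while pixels crossed by a waggling bee score 300+ (the
theoretical maximum for a full-range tone is $(b/2)^2 = 256$; partial-window
tones score lower, real bee edges score high). `calibrate_threshold()`
re-derives the threshold for other window lengths from a bee-free clip by
the same quantile rule. Raising $t_h$ trades detection latency (runs are
clipped harder at their ends) against false positives; the systematic
duration bias this induces is measured by the validation experiments and
stays well inside the tolerated envelope.

Activated pixels are grouped by single-linkage agglomerative clustering cut
at $d_{max1}$ (equivalently, connected components of the distance graph);
`stats::hclust` does the linkage, and a brute-force union-find oracle in the
tests confirms the partition on small inputs. Cluster centroids are tracked
over frames into run candidates by nearest-neighbour linking within
$d_{max2}$, with ties going to the older candidate.

## Filter network

The classifier follows the compact design: two stacked 3D convolutions
(3×3×3 kernels, 8 and 16 channels) with SELU nonlinearities, average
pooling over all three dimensions, dropout (0.1) after the pooling, and a
fully connected sigmoid output. The convolutions use stride 2 in all three
dimensions, which takes the role of intermediate downsampling and keeps a
CPU training run of 800 clips in a couple of minutes; pooling and strides
are configurable in `filter_config()`. Training follows the standard
protocol: random 128-frame subsequences per batch, zero padding of shorter
clips, independent horizontal/vertical flips with probability 0.5, Adam on
binary cross-entropy, and a 20% held-out split fixed by the seed.

Two conditioning choices matter for CPU-scale training budgets. First,
inputs are standardised per clip — zero mean and unit variance over the
real (non-padding) frames, padding frames held at the mean — which is the
regime the SELU self-normalisation assumes; with raw `[0, 1]` inputs the
loss sits on a long, initialisation-dependent plateau before the conv
filters orient toward the temporal oscillation, while standardised inputs
learn immediately. The standardisation also makes the classifier invariant
to illumination gain and offset, matching the detector's invariance.
Second, the learning rate default is 3e-3 rather than a more conservative
1e-3: with only a few hundred optimisation steps at the 800-clip scale the
larger step converges comfortably within budget and the landscape is
benign. The implementation is a small purpose-built one (im2col + BLAS
matrix products, analytic backward pass verified against finite
differences in the tests).

## Orientation model

Subtracting consecutive frames of a laterally oscillating, textureless
blob leaves a signed two-lobe pattern, like a 2D Gabor patch, oriented
along the motion axis. By the Fourier slice theorem this pattern appears in
frequency space as a pair of maxima on the line through the origin at the
motion angle, independent of the blob's position. Per run the pipeline:

1. differences consecutive snippet frames (mean-removed, to suppress a DC
   spike);
2. sums the **magnitudes** of their centred 2D Fourier transforms —
   magnitudes, because the pattern moves with the dancer and complex sums
   would interfere destructively (a test demonstrates the cancellation);
3. multiplies by a ring-shaped difference-of-Gaussians
   $e^{-\rho^2/2k^2} - e^{-\rho^2/2(k/2)^2}$ (surround $\sigma = k$, centre
   $\sigma = k/2$, peak normalised to 1 near radius $k$), with
   $k = I_{size}/(2x)$ where $x \approx 6$ px/frame is the expected lateral
   step — the period of the Gabor pattern is about twice the displacement;
4. extracts the principal axis of the filtered spectrum by PCA, using
   magnitudes as weights (not thresholded maxima — weighting is smoother
   and needs no extra parameter); the body axis is that direction + 90°;
5. disambiguates the two possible headings from the forward drift of the
   per-frame dancer positions: positions are referenced to the mean of the
   first 10% of the run, their directions binned into 36 × 10° bins, and
   the modal direction (circularly averaged over ties) picks the heading.

Angles are degrees clockwise from image "up" everywhere; on a vertical comb
"up" corresponds to the solar azimuth. Runs with a near-isotropic spectrum
(eigenvalue ratio < 1.05) or no forward motion are flagged `degenerate` and
still emitted — the mapping stage's RANSAC can reject them — because
dropping them silently would bias dance statistics.

## Mapping model

Runs embed into $(x, y, t)$ with time in quarter seconds since local
midnight (`time_scale = 0.25`), making the typical drift between a dance's
runs and their time gaps commensurate; single-linkage clustering cut at
`cluster_dist = 60` groups runs into dances, and clusters with fewer than
4 runs are discarded. Within a dance, RANSAC over orientations (100 draws,
single-angle model, 30° inlier window — wide enough that a lone 180° flip
can never join the consensus) selects the inliers; ties in consensus size
resolve toward the smaller circular variance and flag the dance
`weak_mode`. The robust mean angle is the circular mean
$\mathrm{atan2}(\sum \sin, \sum \cos)$ of the inliers; averaging an odd
number of runs warns, because the alternating divergence angle of
successive runs only cancels over even counts.

Field projection: bearing = solar azimuth at the dance's first-run
timestamp + mean comb angle; distance = $f_d \cdot \bar d_w$ with the
linear factor $f_d$ obtained by `calibrate_factor()` from runs signalling a
feeder of known distance (default: 342 m / 582.79 ms). Return durations
are the gaps between consecutive *inlier* runs only; gaps spanning an
excluded outlier are not used. The solar azimuth comes from the standard
NOAA low-accuracy solar position algorithm (declination + equation of
time + hour angle; well under 0.5° error for 1900–2100), implemented in
`solar_azimuth()` and tested against known geometry (equinox sunrise due
east, local solar noon due south, monotone azimuth through a summer day).

## The synthetic renderer and what it does (not) show

All validation runs against `scene_config()` scenes: textureless bright
ellipses (2.5:1 axis ratio, Gaussian-soft edges) on a darker background,
with additive Gaussian sensor noise, optional illumination gradient, and
distractor bees doing a slow random walk. A waggle run advances at
`forward_speed_px_per_frame` (default 0.5 px/frame ≈ 29 mm/s at
1.7 px/mm, about one body length per run) while oscillating sinusoidally
at 13 Hz with `lateral_amplitude_px = 7` — a peak inter-frame lateral step
of ~6 px, matching the 5–7 px/frame lateral displacement the orientation
bandpass is tuned to. One spatial scale (1.7 px/mm, a 14 mm bee ≈ 24 px)
is used for both full scenes and 50×50 snippets: a snippet is a window
tracking the dancer's mean path, which is how exported detections look.
Return phases are semicircular arcs joining run end to the next run start
with alternating handedness; their duration is a free parameter (default
1.5 s) since no canonical distribution exists. All randomness flows from
one explicit seed; identical configuration and seed give bit-identical
frames.

What passing synthetic tests shows: the detector recovers runs and
durations under sensor noise, the decoder recovers orientations to a few
degrees, flips are rare when forward motion exists, and the
cluster/RANSAC/projection chain inverts the generator's geometry. What it
does not show: robustness to occlusion by other bees, comb texture and
glass reflections, non-sinusoidal waggle dynamics, or dancer-follower
crowds — the renderer is deliberately simpler than real footage, so real
recordings should be expected to perform no better than, and usually worse
than, these synthetic figures.

## Validation experiments and problem sizes

`experiment_orientation_error()` (200 runs, uniform random orientations,
noise sd 3), `experiment_duration_error()` (200 single-run scenes,
durations uniform 300–900 ms), `experiment_filter_accuracy()` (400 + 400
clips, 10 epochs) and `experiment_feeder_mapping()` (571 dances, 4–17 runs
each with mean ≈ 5.8, per-run angular spread 14.37°, durations
≈ 583 ± 196 ms, fixed solar azimuth) are the package's standing
experiments; `scripts/acceptance.R` reruns all four from a single seed.
These sizes keep a full validation pass on one CPU core in the tens of
minutes while leaving the error estimates' sampling noise far below the
tolerances being checked.

## Numerical choices and degenerate inputs

* Constant pixel windows normalise to all zeros and can never activate.
* Warm-up windows (fewer than $b$ frames) emit no score.
* The compiled detector slides the complex projections and folds the
  min–max normalisation in as an affine term; it is numerically identical
  (≤ 1e-12 relative) to the direct per-window evaluation, which the tests
  assert against a naive double-loop oracle.
* Clustering ties are broken lexicographically by pixel coordinates, so
  partitions are order-invariant.
* `circular_mean` errors on perfectly opposed angles (zero resultant) and
  guards the floating-point wrap at 360°.
* Homography rectification rejects corner sets with three collinear
  points; bilinear sampling zero-fills outside the source frame.
* Zero-padding snippets for the classifier is exactly idempotent:
  classifying a short clip equals classifying its padded version.

## Known limitations

* Bee identity is not tracked across runs; two dancers waggling
  simultaneously closer than `link_dist` could be merged.
* The duration estimate carries a window-length-dependent systematic bias
  (the validation experiments measure it at a few tens of ms); a
  calibrated deployment can subtract it.
* Direction disambiguation fails (flags degenerate) when the dancer does
  not advance; anatomical head/abdomen detection would be needed to
  resolve those runs.
* The residual comb-orientation-dependent angular error of real dances
  ("Restmissweisung") is not corrected.
* Round dances for nearby resources are out of scope; the 200 ms minimum
  duration actively suppresses their short waggle portions.
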