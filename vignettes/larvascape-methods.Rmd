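---
title: "larvascape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{larvascape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvascape)
```

# The problem

Soft-bodied animals such as *Drosophila* larvae sense their own shape with
multidendritic proprioceptors (vpda, ddaD, ddaE, dbd, vbd, dmd1) embedded in
the body wall of every segment. High-speed volumetric light-sheet imaging of
animals co-expressing a calcium indicator (green, GCaMP6f-like) and a
calcium-insensitive reference fluorophore (red, tdTomato-like) makes it
possible to follow both the 3D motion of these cells and their activity
while the animal crawls or explores freely. `larvascape` implements the
analysis chain such recordings need:

1. geometric correction of raw oblique-sheet stacks (`deskew()`),
2. 3D soma tracking on the static red channel (`track_cells()`),
3. ratiometric activity extraction (`extract_traces()`),
4. contraction-event statistics on inter-cell distances
   (`detect_contractions()` and friends), and
5. a planar two-bar model that decomposes exploratory head motion into
   turning and retraction (`decompose_behavior()`),

together with a ground-truthed synthetic movie generator (`sim_config()`,
`render_movie()`) that every stage is validated against.

# Ratiometric activity: R, R0 and dR/R0

Soma motion through an inhomogeneous illumination field modulates the
apparent brightness of both channels by a common factor. The activity
measure is therefore a background-subtracted channel ratio

$$R(t) = \frac{G(t) - b_G(t)}{D(t) - b_D(t)},$$

where $G$, $D$ are the mean green and red intensities over a cubic ROI that
encompasses the cell body (half-width = cell radius + 1 µm) and $b_G$,
$b_D$ are per-volume background estimates. Any positive common modulation
cancels exactly in $R$. The baseline $R_0$ is the mean of the lowest 10% of
defined ratio samples over the track (at least one sample; we use
$\lceil 0.1 N \rceil$ since no rounding rule is canonical), and the
reported activity is $\Delta R/R_0 = (R - R_0)/R_0$.

Design choices the data do not dictate:

* **Background.** We default to a per-volume dark-floor estimate (mean of
  the voxels at or below the channel's 5th percentile). It is robust to
  cell motion, follows slow lamp drift, and on synthetic movies recovers
  the generator's known zero offset. A user-supplied static box is
  available for recordings with a known empty region.
* **Undefined ratios.** Where the red signal does not exceed background the
  ratio is left undefined and excluded from the baseline, never clamped:
  clamping would bias $R_0$ downward and inflate activity.
* **Control logic.** With a static green marker (GFP instead of an
  indicator) the same pipeline must produce near-zero $\Delta R/R_0$; the
  suite checks this both noise-free (cancellation to numerical precision)
  and under read noise, against a first-order error propagation through the
  ratio including the selection bias of the lowest-decile baseline (the
  expected mean of the lower 10% tail of a normal lies 1.755 sd below its
  mean).

# Tracking

Somata are seeded manually (labeled 3D points at the first volume) and then
followed frame to frame on the red channel: within a sphere of 15 µm around
the previous position, the centroid of red intensity is iterated to
convergence (< 0.1 voxel, max 20 iterations), with an adaptive threshold at
half the window maximum. Numerically we weight each voxel by its intensity
*in excess of* the threshold: the estimator is then continuous in the data,
which removes the grid-dependent bias and the threshold-crossing jitter a
hard cutoff produces (measured on noise-free renders: 0.26 µm maximum error
with the hard cutoff, 0.07 µm with excess weights).

When candidates of neighboring tracks converge within one cell radius,
identities are re-assigned by minimal total displacement over the
conflicting cluster (exhaustive over the cluster, deterministic tie-break
in `cell_id` order), and the cluster is flagged `low` for supervision —
the code has no criterion for when a human *must* intervene, so it flags
instead. Windows with no signal above background mark the track `lost`;
lost tracks are truncated, never extrapolated, and `apply_corrections()`
resumes tracking forward from a manually supplied position. Tracking is
deterministic and invariant to positive rescaling of the movie.

# Contraction events and time normalization

Segment contraction is proxied by the Euclidean distance between a neuron
and its homolog in the adjacent segment. Because crawl speed and response
amplitude vary across animals, events are put on a common footing before
averaging:

* **Resting length** = 90th percentile of the distance trace (robust to
  how long the segment dwells contracted).
* **Detection**: 0.3 s moving average (suppresses frame noise at 10
  volumes/s without distorting 0.7–2.5 s contractions; set to 0 for
  analytic traces), local minima with depth ≥ 15% of resting length.
* **FWHM**: width over which the excursion exceeds half its peak, with
  sub-sample linear interpolation of both crossings.
* **Exclusion**: events whose distance does not re-attain 95% of resting
  length before the next event are dropped (`no-return`), and at most the
  first two surviving events per neuron enter averaging
  (`max-two-per-neuron`; chronological order, since no other rule is
  canonical).
* **Normalization**: time is mapped to $(t - t_{\min})/\mathrm{FWHM}$ so
  that 0 A.U. is maximal contraction and 1 A.U. is one FWHM; distance and
  activity are linearly interpolated onto the fixed grid $[-3, 3]$ A.U. in
  steps of 0.05 (wide enough to hold the phase windows with headroom), and
  activity is optionally amplitude-normalized to a peak of 1 so strongly
  responding cells do not dominate averages.

Phase statistics use the contraction window $[-1, 1]$ A.U. (2 × FWHM
centered on maximal contraction; reported value = max $\Delta R/R_0$) and
the resting window $[-1.5, -1]$ A.U. (0.5 × FWHM immediately prior;
reported value = mean). Activation timing is the first *rising* crossing of
half the within-window maximum (activation, not decay, is what sequential
ordering is about), and per-type lags are tested with a one-tailed paired
t-test on per-pair half-max times; zero-variance differences are refused
rather than reported as p = 0 or 1.

# The two-bar exploration model

During exploration the head both turns and retracts. With the left/right
dorsal cells of two adjacent segments as corners D1L/D1R (anterior) and
D2L/D2R (posterior), the anterior body is modeled as two rigid bars of
length $2p$: the posterior bar is the reference frame, the anterior bar
sits at midpoint separation $S(t)$ and is rotated by $\theta(t)$ about the
posterior midpoint. The coordinate construction (`pose_to_positions()`) is
the authoritative exact model; the ipsilateral inter-cell distances it
implies are algebraically

$$r_{L,R} = \sqrt{(p - p\cos\theta)^2 + (S \mp p\sin\theta)^2},$$

and the linearization is $r_R = S + p\sin\theta$, $r_L = S - p\sin\theta$.
Under the linear model the difference $r_L - r_R = -2p\sin\theta$ depends
only on turning and the sum $r_L + r_R = 2S$ only on retraction — the
"common mode rejection" that lets left/right differences and sums of both
positions and calcium signals separate the two behaviors.

Sign convention: $\theta$ is counterclockwise in the (left-right, anterior)
plane, so positive $\theta$ swings the head toward the animal's left and
shortens $r_L$. The linearization error over the physiological grid
$p = 25$ µm, $S \in [75, 125]$ µm, $|\theta| \le 30°$ is computed by
`approximation_error()`; its maximum sits at the most-retracted, most-turned
corner of that grid (the bound tightens quickly as $S$ grows — below 0.12%
for $S \gtrsim 90$ µm at 30°).

`decompose_behavior()` projects the four 3D tracks onto their least-squares
body plane (the model is planar, real tracks are not), estimates
$\hat p$ as half the mean D2L–D2R distance, and reports two estimator
families side by side:

* the **linear-model metrics** the common-mode argument is about
  (`turning_metric_um`, `retraction_metric_um`, and
  $\hat\theta = \arcsin((r_L - r_R)/(-2\hat p))$, clamped and flagged if
  the argument leaves $[-1, 1]$), and
* **exact inversions** that undo the coordinate model directly
  (`theta_exact_rad` from the signed in-plane angle between the bars,
  `s_exact_um` from the inter-bar midpoint distance). These are the right
  choice for parameter recovery; the linear metrics are the right choice
  for interpreting left/right calcium sums and differences.

Calcium lags movement (deformation drives the indicator), so
`metric_correlations()` searches delays one-sidedly, on a grid of one
volume period, up to a caller-set maximum.

# The synthetic generator

The generator produces the statistical structure the analysis assumes, with
known ground truth, under two modes:

* **Crawl**: segment $i$ has length
  $L_i(t) = L_0\,(1 - A\,e^{-(t - t_i)^2/2\sigma^2})$ with onsets advancing
  anteriorly at the wave speed — a posterior-to-anterior peristaltic wave.
  Cell y positions are cumulative sums of segment lengths from the fixed
  tail, so a cell's distance to its posterior homolog *is* its segment
  length; left/right homologs sit at ±p.
* **Explore**: smooth seeded $\theta(t)$ (two low-frequency sinusoids) and
  strictly positive $S(t)$, rendered through the two-bar corner
  construction.

Calcium follows $\dot c = g\,u(t) - c/\tau$ with $u$ the rectified
fractional deformation of the cell's segment (stretch-rectified for the
dbd analog, contraction-rectified for all others) — the simplest transfer
function consistent with deformation-coupled activity; it is a modeling
stand-in, not an inference about the biology. The ODE is integrated with an
exact zero-order-hold update, so decay and step-response closed forms hold
to machine precision at sample times. Per-type onset delays emulate
sequential activation. Rendering: isotropic Gaussian somata (sd = cell
radius) sampled at voxel centers, static red amplitude, green
$\propto (1 + c)$, a common sinusoidal intensity modulation on both
channels (the motion-induced brightness artifact the ratio must cancel),
additive Gaussian read noise (Poisson shot noise available), clipped at 0.

Defaults are the regime the pipeline targets: 10 volumes/s, indicator decay
0.4 s, segment rest length 80 µm, half-width 25 µm, wave amplitude 0.35
with σ = 0.4 s (contraction FWHM 2.355σ ≈ 0.94 s, inside the observed
0.7–2.5 s range), 10% intensity modulation, red soma peak 100 a.u. with
noise sd 5–10 (SNR 20–10). A single integer seed makes every product
bit-reproducible; sub-streams are derived from it per component.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: optical anisotropy and scattering (somata are
isotropic Gaussians), dendrite morphology and subcellular signals,
non-rigid soma deformation, tracking-frame drops, slow bleaching (the
ratio absorbs it only insofar as it is common to both channels), and
behavioral irregularity beyond the smooth kinematics above.

# Validation problem sizes

The test suite exercises the full chain at deliberately compact sizes: 3–4
segments at 50–60 µm rest length and 5–6 s of recording for rendered-movie
tests (tracking oracle at SNR 10: RMS error < 1 µm, zero identity swaps);
9 segments × 13 s, 100 seeded replicates, for the sequential-activation
power check (8 pairs, delays of 1.5× and 3× the volume period, one-tailed
paired t-tests at α = 0.05); 3 s of explore mode at SNR 10 for
θ/S recovery (< 1° and < 1 µm). Event geometry is validated on analytic
traces (triangular dip: depth 40 µm, FWHM exactly 1.0 s; Gaussian dips:
FWHM within one volume period of 2.355σ).

# Known limitations

* Seeding is manual by design; there is no automatic cell detection.
* The deskew applies the oblique-angle shear only — no deconvolution, no
  resolution modeling, and the sheet angle must be supplied.
* The two-bar model is planar and rigid; out-of-plane bending shows up as
  projection error, and $\hat p$ assumes the bar length is fixed.
* Conflict resolution is exhaustive over conflicting clusters and refuses
  clusters larger than 7 cells (flagging them for supervision instead).
* TIFF metadata lives in a JSON sidecar next to the image file; moving one
  without the other makes the movie unreadable (by design: the reader
  refuses to guess voxel spacing).
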