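---
title: "Methods: electrode localization and SOZ indices in seegquake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrode localization and SOZ indices in seegquake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegquake)
```

seegquake implements the computational core of a presurgical SEEG
evaluation: locating depth-electrode contacts in a post-implant CT volume,
and ranking channels by two seizure-onset-zone (SOZ) indices — the ictal
Epileptogenicity Index (EI) and the interictal High-Frequency Events Index
(HI). This vignette explains the models, the tunable parameters and their
defaults, the numerical choices made where the design was genuinely open,
and what the synthetic-data experiments do and do not show about real data.

## Electrode localization

### Model and pipeline

A skull-stripped CT co-registered to anatomical space contains essentially
two intensity populations: brain tissue and metal. Electrode contacts
appear as bright blobs arranged along straight (occasionally slightly
bent) shafts at a fixed manufactured pitch. The pipeline exploits exactly
this structure:

1. **Presmoothing** (`presmooth_sigma_mm`, default 0.5 mm). A light
   separable Gaussian suppresses per-voxel noise before thresholding and
   center-of-mass refinement. Smoothing a rotationally symmetric blob does
   not move its center, so the step is bias-free for the quantity of
   interest; it mainly removes isolated noise voxels that would otherwise
   cross the threshold and it reduces the noise-driven jitter of the
   center-of-mass fixed point.
2. **Thresholding** (`threshold_rule`, default `relative:0.5`). The
   default cutoff is half of the robust intensity maximum (the 99.99th
   percentile of nonzero voxels). In a skull-stripped CT the brightest
   voxels are metal, so half of that value is far above any tissue
   intensity, and the rule is invariant to intensity scaling and voxel
   size. Otsu's method is available (`"otsu"`) but is documented as suited
   to clearly bimodal histograms: blob profiles taper continuously into
   the background and the metal class is outnumbered roughly 100:1 by
   brain voxels, a regime in which single-pass Otsu settles inside the
   background mode. Percentile and absolute rules are provided for manual
   override.
3. **3D Hough transform** (`hough_lines_3d`). Line candidates are voted
   over a discretized parameter space: directions are the
   antipode-deduplicated vertices of a three-times subdivided icosahedron
   (321 directions, angular spacing below 5 degrees), crossed with the
   line anchor expressed in the 2D plane orthogonal to each direction and
   binned at 1 voxel. Shafts are extracted by iterative peak peeling:
   claim the best cell's line, remove its inliers (default inlier radius
   2 mm, converted to voxels), repeat until the next peak drops below
   `min_votes` (default: a quarter of the first peak's votes, floored at
   10). This vote-based stop avoids asking the user for the electrode
   count while still allowing an explicit `n_electrodes` override.
4. **Gaussian-mixture clustering** (`cluster_electrodes`). A
   full-covariance mixture with one component per detected line assigns
   every cloud point to an electrode. Initialization comes from the Hough
   result — one-hot responsibilities of the nearest detected line — which
   places component means at the Hough centroids and makes the starting
   covariances elongated along the shaft directions. This is the point of
   the Hough stage: it replaces the random restarts that make plain
   mixture clustering unreliable on line-shaped clusters. A default
   conjugate prior regularizes covariances so noiseless, exactly
   collinear clusters cannot collapse. With deterministic initialization
   the fit itself is deterministic.
5. **Shaft axis regression** (`fit_shaft_axis`). Total least squares (the
   leading principal axis through the member centroid), chosen over
   coordinate-pair ordinary regression because it is rotation-invariant
   and treats all axes symmetrically. The fit is trimmed twice (drop
   points farther than 3 then 2 voxels and refit) so stray
   supra-threshold noise voxels cannot tilt the axis.
6. **Head-point selection** (`find_head_point`). The member projections
   onto the axis define the shaft endpoints; the head (deepest contact)
   is the endpoint nearer the volume's center of intensity mass,
   reflecting the anatomical fact that the deepest contact lies closest
   to the center of the brain. Endpoints are taken from the largest
   contiguous run of near-axis projections, so isolated noise voxels
   beyond the physical shaft cannot masquerade as an endpoint. Exact ties
   break toward the lower flattened voxel index.
7. **Center-of-mass contact segmentation** (`segment_contacts`). The
   first contact is found by iterating the intensity-weighted centroid of
   a cube around the head point (`cube_mm`, default 2 mm, matched to the
   physical contact size); each subsequent contact starts one pitch
   (`pitch_mm`, default 3.5 mm) along the axis and is converged the same
   way. Voxels of the electrode's own cluster receive double weight — the
   geometric restriction that keeps the walk on the shaft when another
   bright structure is nearby. Two implementation details matter:
   * intensities are sampled by trilinear interpolation on a 0.25 mm grid
     inside the cube, and the double weight is applied through the
     *interpolated* membership fraction of a smooth tube around the
     fitted axis (radius 2.5 voxels, spanning the shaft core plus one
     pitch). A discrete supra-threshold member set is asymmetric around
     the contact center (noise decides borderline voxels), and doubling
     it verbatim was measured to bias the converged center by about
     0.08 mm; the tube is rotationally symmetric about the axis and
     leaves the perpendicular centroid unbiased while confining the walk
     identically.
   * iteration runs to the fixed point (`com_tol_voxel` 0.01 voxels,
     `com_max_iter` 30) rather than stopping after the one or two
     iterations that are typically "enough". Stopping early leaves each
     contact near its stepped starting point, which lies on the fitted
     straight axis by construction — that flatters any
     distance-to-regressed-axis metric without actually localizing the
     contact. Converging fully makes the reported geometry an honest
     property of the image. If the iterate enters a two-point cycle (two
     comparable bright spots), the brighter candidate is returned — the
     guard against the oscillation that otherwise loops forever between
     two merged contacts.
   Stepping stops at `max_contacts` (16), when the stepped point leaves
   the shaft core's bounding box dilated by one pitch, when the converged
   intensity falls below the extraction threshold (off the shaft end), or
   when the converged point advances less than half a pitch (stalled) —
   the last rule also guarantees strictly monotone contact projections.
   The termination rule is not fully constrained by the underlying
   method description; this three-plus-one-condition stop is our
   documented choice.
8. **Geometric QC** (`geometry_qc`). Two indirect validation metrics that
   need no manual gold standard: the perpendicular distance of each
   contact to a line re-regressed through the *final contact
   coordinates* (not the voxel cloud — the metric is about where the
   contacts ended up), and the deviation of consecutive contact distances
   from the manufactured pitch.

Conventions throughout: voxel indices are 0-based, user-facing coordinates
are mm through the NIfTI affine, and all signal intervals are half-open
`[start, end)`.

### What the synthetic volumes emulate

`synth_volume` renders a dim ellipsoidal "brain" (about 10% of blob peak,
zero outside, as after skull-stripping), additive Gaussian noise (default
SD 10% of blob peak), and Gaussian-profile contacts (FWHM equal to the
2 mm contact diameter) along straight or circular-arc-bent shafts with
8–16 contacts at 3.5 mm pitch — the geometry of common clinical depth
electrodes. The default grid is 0.7 mm isotropic over a 96 mm field of
view, emulating thin-slice post-implant CT; at substantially coarser
resolution the 0.1 mm axis-distance scale of the QC metrics approaches a
tenth of a voxel and becomes noise-limited. Blob tails at 3.5 mm pitch
partially merge, reproducing the known hard case of adjacent contacts
that blur together.

Not emulated: skull or dental artifacts (removed by skull-stripping
upstream), beam-hardening streaks, anisotropic slice profiles, and
registration error between CT and anatomical space. Passing the geometric
criteria here shows the algorithm recovers the geometry it models; it
does not certify performance on artifact-heavy clinical images, where
visual verification remains mandatory.

On these conditions (20 volumes, 8 electrodes each), the pipeline
recovers every planted contact; the acceptance script reports the
axis-distance and pitch-calibration statistics it computes at run time.

## Ictal module: Epileptogenicity Index

Per channel, the EI combines *when* the high-gamma discharge starts and
*how strong* it is shortly after seizure onset:

1. Filter to the high-gamma band (60–140 Hz, order-5 Butterworth) after a
   50 Hz notch (second-order IIR, Q = 30). Both are applied
   forward–backward (zero-phase): a causal filter's group delay would
   shift detected onset times, which are the quantity of interest. The
   notch Q is stated by the method only for the interictal path; we reuse
   Q = 30 here.
2. Square the signal and smooth with a centered 500 ms moving average
   (one-sample step; the window shrinks at the recording edges), then
   divide each channel by its mean over a manually chosen baseline
   segment, giving the normalized high-frequency energy (NHFE). Baseline
   NHFE averages exactly 1 per channel, and every downstream quantity is
   invariant to rescaling the raw recording.
3. Threshold per channel at `max(baseline NHFE) + 10 * sd(baseline NHFE)`
   (sample SD, n−1; the convention is not fixed by the formula). The
   onset is the first target-segment sample strictly above the
   threshold.
4. Rank onset channels by onset time; the time coefficient is the
   reciprocal rank (1, 1/2, 1/3, ...). Simultaneous onsets are ranked in
   channel order — ties are not discussed by the underlying method, and
   distinct ranks keep the rank sequence gap-free. The energy coefficient
   is the mean NHFE over the 250 ms window starting at the *globally
   earliest* onset ("right after the earliest onset time" is singular —
   one window anchors all channels; using NHFE rather than raw energy
   keeps the normalization chain consistent, though the description
   leaves this open). `EI = TC * EC`; channels with no onset get
   `TC = EI = 0` so the output always covers every channel.

`synth_ictal_recording` plants band-limited 60–140 Hz bursts whose
amplitude ramps in with a saturating exponential (time constant 1 s,
configurable) on pink-noise baselines — a smooth NHFE rise resembling
real seizure onsets rather than a step. With onsets staggered by 0.5 s at
SNR 5, the EI ranking recovers the planted order essentially always; with
no planted onset, the 10-sigma threshold makes false onsets rare.

## Interictal module: High-Frequency Events Index

Per channel: notch (50 Hz, Q = 30), order-5 Butterworth band-pass to
80–250 Hz (user-adjustable), and the modulus of the analytic signal
(Hilbert transform) as the envelope. The event threshold is synergistic:
`2 * max(median_i, median_global)`, where `median_i` is the channel's
envelope median and `median_global` pools all channels and samples (the
scalar use of the global term implies pooling, not a per-sample median).
Supra-threshold runs (strict inequality, as in the ictal rule) are
merged when separated by less than 20 ms, then runs shorter than 50 ms
are excluded. The order — merge first, filter second — changes the
counts and is pinned by test: a 40 ms burst 10 ms from a 60 ms burst is
one event, not zero-then-one. HI is the per-channel event count (with a
per-minute rate for convenience).

Two properties of this detector deserve emphasis, both established
empirically by the test suite:

* **Event counts are not monotone in the threshold.** Raising a
  threshold can split one long event into two shorter ones that both
  clear the 50 ms filter (the dip between them exceeding the 20 ms merge
  gap). The total supra-threshold time is monotone; the count is not.
* **A relative 2×median threshold has an irreducible false-event floor
  on Gaussian backgrounds.** The envelope of band-limited Gaussian noise
  is Rayleigh, which exceeds twice its median on 6.25% of samples
  (2^-4, independent of band, sampling rate, or spectral slope). After
  merging and duration filtering, roughly 6–12 false events per minute
  per channel remain on the pink-noise background of
  `synth_interictal_recording`. At clinically plausible planted-ripple
  rates (tens per minute), event-level precision therefore saturates
  near 0.8 — a property of the detector's threshold rule, not of the
  implementation — while recall of planted events at SNR ≥ 3 exceeds
  0.95. As a *relative* index across channels HI is unaffected (the
  floor is common to all channels); the absolute counts should not be
  read as HFO rates.

`synth_interictal_recording` plants Tukey-windowed (flat-plateau)
ripple-band bursts, carrier 100–200 Hz, durations 60–150 ms, gaps of at
least 100 ms, amplitude calibrated per channel so the mean in-event
envelope is `event_snr` times that channel's envelope median. A plateau
rather than a narrow Gaussian envelope keeps a 60 ms event above
threshold for most of its nominal duration, so the 50 ms duration filter
measures the detector, not the window shape.

## Evaluation

`roc_auc` computes the AUC as rank-based concordance (the probability a
random positive channel outranks a random negative one, ties counting
one half) — stated explicitly because tie conventions differ between
implementations; the test suite pins it to a brute-force all-pairs count
and to an independent ROC implementation. `match_contacts` matches found
to true contacts greedily, one-to-one, within half a pitch (1.75 mm), so
a found contact cannot be credited to an adjacent true contact.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; the generators
restore the caller's RNG state. The validation batch used by the tests
and the acceptance script is 20 volumes of 8 electrodes (about 1,700
contacts) at 0.7 mm resolution, and the index experiments use 4–6
channel recordings of 24–60 s at 1000 Hz — sizes chosen so the whole
suite runs on a laptop-class single core in minutes while keeping the
statistics stable.

## Known limitations

* Registration, skull-stripping, and anatomical labeling are upstream of
  this package; it consumes an already skull-stripped, co-registered
  volume.
* The EI here is the simplified onset-rank formulation, not the original
  energy-ratio EI of Bartolomei and colleagues.
* Contact counts on real data should be visually verified; center-of-mass
  convergence can skip a contact on images with severe artifacts, and
  bent electrodes widen both QC distributions (reproduced by the
  `bend_amplitude_mm` option).
* HI absolute counts include the detector's false-event floor (above);
  interpret HI comparatively across channels of the same recording.
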