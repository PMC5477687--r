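---
title: "Quantifying brown-adipose-tissue activation from thermal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brown-adipose-tissue activation from thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoroi)
```

## The measurement problem

Active brown adipose tissue (BAT) dissipates chemical energy as heat. In
adult humans the largest depot sits in the cervical–supraclavicular (C-SCV)
region, close enough to the surface that its activation warms the overlying
skin. Infrared thermography therefore offers a cheap, radiation-free way to
monitor BAT: film the supraclavicular skin with a radiometric camera,
delineate the "hot" patch over the depot, and convert its area and
temperature into radiated power. `thermoroi` implements that pipeline —
segmentation, metric calibration, radiometric quantification, and the
study-level responder analysis — together with a synthetic thermogram
generator so every stage can be validated against known ground truth.

The pipeline consumes sequences of per-pixel skin-temperature matrices in
°C (5 s of video at 30 Hz, i.e. 150 frames per data point, in the protocol
the defaults follow) and produces, per body side, a sequence-averaged
region-of-interest (ROI) pixel count, metric area $A$ (m²) and mean
temperature $T$ (K), and finally the radiated power
$W = \varepsilon \sigma A T^4$.

## Seeded region growing with a temperature tolerance

Simple thresholding of the hottest quartile (the earlier practice this
method replaces, kept here as `threshold_segment()` for comparison) ignores
spatial structure and returns scattered pixel clusters. The detector in
`grow_region()` instead grows a single connected region from a seed:

1. **Seed.** The hottest valid pixel inside a pre-defined search window
   over the left or right C-SCV area (`select_seed()`). Ties go to the
   smallest `(row, col)` in row-major order so results are bit-reproducible.
2. **Initial region.** All valid pixels within Chebyshev radius
   `seed_region_radius` of the seed (default 1, i.e. a 3×3 patch — the
   smallest neighbourhood with a stable mean). Invalid pixels shrink the
   patch rather than aborting.
3. **Growth.** Let $H$ be the frontier: every unallocated valid pixel
   8-adjacent to the region. For $x \in H$ the deviation is
   $\delta(x) = |T(x) - \text{mean}(A_i)|$ against the *current* region
   mean. The frontier pixel with minimal $\delta$ is admitted while
   $\delta \le T_t$; the mean is updated after every admission (the mean is
   dynamic, not frozen at the seed). Equal deviations are again resolved
   row-major.
4. **Stop.** When the best frontier deviation exceeds the tolerance $T_t$,
   the frontier empties, or the region reaches `max_region_fraction`
   (default 0.5) of the searched pixels — a guard against runaway growth on
   low-contrast frames.

The admission comparison is non-strict ($\delta \le T_t$), and growth is
confined to the search window. Pixels in the fiducial temperature band
(28–31 °C by default) are masked out of the window before segmentation so
the cool calibration disks can never be absorbed into a region.

`segment_sequence()` re-seeds and re-grows on every frame independently and
averages the per-frame pixel count and mean ROI temperature arithmetically
across frames; frames that cannot be segmented are dropped from the average
with a warning.

### Choosing the tolerance

$T_t$ is the one genuinely subject-specific parameter: the original
protocol tuned it by hand per subject, because no single preset worked for
everyone. Two routes are provided:

* pass an explicit `t_t` to `seg_params()`, or
* `auto_tolerance()`, a reproducible surrogate that scans a tolerance grid,
  records the grown region size at each value, and returns the midpoint of
  the longest run of constant size — the plateau of the size-versus-
  tolerance curve where segmentation is insensitive to the exact value.
  This is an extension of the manual procedure, not a reproduction of it.

### Seeding radius and edge shape

Two practical interactions are worth knowing. On a *smooth-edged* hotspot
the 3×3 default seed patch stabilises the initial mean against pixel noise.
On a *hard-edged* plateau, however, the hottest noisy pixel falls on the
plateau boundary a noticeable fraction of the time, and a radius-1 patch
then straddles the edge: the diluted initial mean sits between plateau and
background, and with $T_t$ near half the plateau height both populations
become admissible — growth runs away to the size cap. For such scenes use
point seeding (`seed_region_radius = 0`); the recovery tests do. This
mirrors the per-subject parameter tuning the protocol itself prescribes.

## Metric calibration from fiducial disks

Four aluminium-foil disks (5 mm diameter) on the skin delineate an
18 cm × 8 cm rectangle on the body plane. Foil reflects the cool
surroundings, so the disks image at roughly 28–31 °C against ~33 °C skin
and are trivially detectable: `detect_fiducials()` thresholds that band,
labels connected blobs (EBImage), discards blobs under `min_blob_px`
pixels, requires exactly four, and orders sub-pixel centroids
geometrically (upper-left, upper-right, lower-left, lower-right).

`estimate_transform()` fits the exact 3×3 homography mapping homogeneous
pixel coordinates to cm on the body plane by direct linear transform on the
four correspondences — four points determine the 8 degrees of freedom
exactly, so the residual at the markers is numerical noise. A full
homography rather than an affine map is used because the four markers span
a rectangle on a three-dimensional plane that is generally not parallel to
the sensor; in the frontal view it degrades gracefully to a uniform scale.

ROI area integrates the transform's local scale over the mask: each member
pixel contributes the absolute Jacobian determinant of the pixel→cm map at
its centre ($|\det J| = |\det H| / |g x + h y + i|^3$ for third row
$(g, h, i)$). For affine transforms this reduces exactly to
pixel count × constant. Because both fiducials and ROI move together under
pose drift, the recovered *metric* area is invariant to scene translation
and to rendering resolution — the point of calibrating at all.
Calibration uses the first frame by default and is held fixed;
`calibrate_sequence(per_frame = TRUE)` re-estimates per frame.

## Radiated power

`heat_output()` applies the Stefan–Boltzmann law
$W = \varepsilon\,\sigma\,A\,T^4$ with skin emissivity
$\varepsilon = 0.98$ and $\sigma = 5.676\times10^{-8}$ W m⁻² K⁻⁴ (the
method's printed value, kept as the default so published arithmetic
reproduces; override via `phys_constants()`). Temperatures convert °C→K
with 273.15 exactly, and a 300–315 K validation band catches the classic
Celsius-for-Kelvin bug before it silently inflates $T^4$ by four orders of
magnitude.

The law is applied to the sequence-averaged $(A, T)$ — mean-then-power.
Because $T^4$ is convex the alternative order (power per frame, then mean)
differs slightly; `quantify_sequence()` reports both (`watts`,
`watts_per_frame_mean`), with mean-then-power as the headline number. Left
and right sides are summed by `total_heat()`, and stimulation responses are
expressed as `percent_change_heat()` relative to baseline.

## Study-level statistics

`classify_groups()` implements the responder rule: subjects whose percent
change in total heat output strictly exceeds the cohort
mean + 1 standard error are "high-BAT", the rest "low-BAT". The SE uses
the sample SD ($n-1$ denominator) over $\sqrt{n}$. Paired comparisons and
Pearson correlations (`paired_t_test()`, `correlate()`) wrap the standard
`stats` tests with explicit zero-variance guards. Longitudinal
two-condition data are summarised by `timepoint_contrasts()` — per-
timepoint paired t tests on baseline-adjusted changes — a transparent
alternative to a fitted longitudinal structural model, which is out of
scope here. No multiplicity correction is applied (α = 5%).

## The synthetic generator: what it does and does not emulate

`generate_sequence()` renders, deterministically given its seed: a warm
skin background (33 °C default, optional linear gradient), elliptical
hotspot plateaus `delta_t_c` above background with a sigmoid edge of
configurable width, four cool fiducial disks placed at the layout corners
under a known pixel-per-cm scale, i.i.d. Gaussian pixel noise, and rigid
per-frame translation ("pose drift"). Ground truth is returned alongside:
per-frame plateau masks and the exact pixel→cm transform.

Defaults follow the acquisition protocol where one exists — 30 Hz,
150 frames, 18 cm × 8 cm marker rectangle, 5 mm disks, disks at 29.5 °C
(mid-band) — and otherwise values a thermographer would call plausible:
33 °C background, 2 °C hotspot elevation (supraclavicular hot regions sit
a degree or three above surrounding skin), 0.1 °C pixel noise
(high-end microbolometer NETD is ~0.05 °C; 0.1 is conservative), 4 px/cm
(a 320×240 camera framing a ~60 cm field of view).

The edge-width parameter deserves a note. A real activation boundary is a
sharp change in the dermal temperature gradient, not a true step; the
default sigmoid width of 0.4 px reflects that. But with a smooth edge the
"true plateau mask" is itself ambiguous at the boundary band — roughly 2%
of the area for the default geometry — so *exact*-recovery claims would be
testing the scene's ambiguity, not the detector. The ground-truth-recovery
tests therefore use the step-edge limit (`edge_width_px = 0`), where the
true mask is unambiguous and any discrepancy is attributable to the
algorithm. Passing those tests shows the detector recovers a well-posed
target through noise, drift and calibration; it does not certify
performance on real anatomy, textured skin, non-rigid pose change, or
vascular confounds, none of which the generator models.

`generate_cohort()` draws per-subject baseline heat outputs and percent
changes from a responder/non-responder mixture. Defaults emulate the study
design: 24 subjects, responder fraction 0.25, baseline total ~1.5 W
(the order of magnitude $\varepsilon \sigma A T^4$ gives for ~15 cm² per
side at ~35 °C), non-responder percent change 43 ± 15 and responder
85 ± 15 — back-computed from the reported group heat deltas over that
baseline. Classifier-recovery tests use wider separations on top of these
study-shaped conditions, as their purpose is label-recovery scoring.

## Numerical and degenerate-input choices

* All ties (seed selection, frontier admission) break to the smallest
  `(row, col)` row-major — reproducibility over any claim of optimality.
* The region mean is an exact running sum updated per admission, not a
  frozen seed value and not a re-summation (O(1) per step).
* Non-finite pixels are invalid everywhere: never seeds, never admitted,
  never counted in means; an all-invalid frame is recorded as missing and
  excluded from sequence averages with a warning.
* 16-bit storage quantizes to `scale/2` = 0.005 °C at the default
  0.01 °C/count; count 65535 is reserved for invalid pixels.
* Homographies are solved by SVD on the 8×9 design matrix (no
  normalisation needed at these conditioning levels; recovery error is
  ~1e-11 over randomised transforms) and normalised so the
  largest-magnitude entry is 1.
* Degenerate inputs error loudly: empty sequences, ragged frames, missing
  metadata, <4 or >4 fiducial blobs, collinear correspondences, zero
  baseline power, zero-variance t tests and correlations, n < 2 cohorts.

## Problem sizes in the shipped tests

The test-suite and acceptance-script workloads are sized for tight
feedback loops while still exercising every contract: 96×128 px scenes
(3–5 frames for recovery runs, one 150-frame 48×64 sequence for the
frame-bookkeeping check), 1,000 random ≤7×7 frames for oracle
equivalence, 200 for tolerance monotonicity, 50 seeded noisy scenes for
recovery, 100 random homographies, and 100 + 200 seeded cohorts for
classifier recovery. The full suite runs in well under a minute.

## Known limitations

* Skin-surface radiation underestimates depot thermogenesis: heat reaches
  the skin through subcutaneous tissue, so the watts reported are a lower
  bound modulated by fat thickness. No convective/conductive correction is
  attempted.
* The three-pose acquisition protocol (front/left/right head turns) is
  treated as independent scenes; ROI identity is not tracked across poses.
* The calibration plane is assumed rigid and planar between the four
  markers; non-planar chest-surface curvature biases the Jacobian area
  integral.
* Vendor radiometric video formats are out of scope; sequences must be
  exported to the package's TIFF-stack or CSV interchange formats first.
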