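# thermoroi

Quantify brown-adipose-tissue (BAT) activation from infrared thermography
video of the supraclavicular region.

Active BAT warms the skin over the cervical–supraclavicular (C-SCV) depot.
Given a sequence of per-pixel skin-temperature frames (°C), `thermoroi`:

1. **detects the hot region of interest** on every frame with a modified
   seeded region growing (SRG) segmentation: seed at the hottest pixel of a
   pre-defined search window, then repeatedly admit the 8-adjacent frontier
   pixel whose temperature deviates least from the running region mean,

   δ(x) = |T(x) − mean(Aᵢ)|,  admit argmin δ while δ ≤ T_t,

   stopping at the tolerance `T_t` — yielding one closed, connected region
   where plain quartile thresholding (`threshold_segment()`, included as
   the baseline) scatters disconnected clusters;
2. **calibrates pixels to centimetres** from four cool aluminium-foil
   fiducial disks (an 18 cm × 8 cm rectangle on the body plane)
   via an exact four-point 3×3 homography, integrating the transform's
   Jacobian over the mask for metric ROI area;
3. **converts to radiated power** with the Stefan–Boltzmann law
   `W = ε σ A T⁴` (ε = 0.98, σ = 5.676×10⁻⁸ W m⁻² K⁻⁴) from the
   sequence-averaged area (m²) and temperature (K);
4. **classifies responders**: subjects whose percent change in total heat
   output strictly exceeds the cohort mean + 1 SE form the high-BAT group;
   paired t tests and Pearson correlations cover the usual study-level
   comparisons.

A synthetic thermogram generator (`generate_sequence()`,
`generate_cohort()`) renders scenes with known plateau masks, a known
pixel→cm transform and known responder labels, so the entire pipeline is
testable without human data.

## Worked example

```r
library(thermoroi)

# a 5 s / 150-frame synthetic scene: 33 C skin, one 2 C-warmer plateau,
# four 29.5 C fiducial disks, 0.1 C pixel noise
hs    <- hotspot_spec(center = c(40, 80), semi_axes = c(8, 11),
                      delta_t_c = 2, edge_width_px = 0, side = "left")
scene <- scene_spec(dims = c(96, 128), hotspots = list(hs),
                    noise_sd_c = 0.1, n_frames = 150, seed = 7)
gen   <- generate_sequence(scene)
gen$sequence
#> <thermal_sequence> 150 frames of 96 x 128 px, 30 Hz (5 s), scale 0.01 C/count, offset 0 C

win <- search_window(25, 70, 55, 110, side = "left")
q   <- quantify_sequence(gen$sequence, win,
                         seg_params(t_t = 1, seed_region_radius = 0))
q$segmentation
#> <sequence_segmentation> side left: 150/150 frames, mean ROI 275.0 px at 34.999 C
sprintf("area %.6g m^2, T %.2f K -> %.4f W",
        q$measurement$area_m2, q$measurement$temp_k, q$watts)
#> "area 0.00171875 m^2, T 308.15 K -> 0.8620 W"
```

The detector averaged 275 ROI pixels at 34.999 °C over the 150 frames;
through the fiducial calibration (4 px/cm here) that is 17.19 cm² of skin
at 308.15 K, radiating 0.862 W. The generator's ground truth — the true
plateau mask pushed through the true transform — gives the same 0.00171875
m² and 0.8620 W, i.e. exact recovery of this scene.

Study-level, on a simulated 24-subject cohort:

```r
classify_groups(generate_cohort(seed = 1)$pct_change)
#> <group_assignment> cutoff 58.14% (mean 53.35 + SE 4.79): 8 high-BAT, 16 low-BAT
```

## Command line

A thin Rscript exposes the same pipeline
(`system.file("exec", "thermoroi.R", package = "thermoroi")`):

```sh
thermoroi.R simulate  --config scene.json --out sim/
thermoroi.R segment   --seq sim/sequence.tif --window side=left,25,55,70,110 \
                      --tt 1 --seed-radius 0 --out roi.json
thermoroi.R calibrate --seq sim/sequence.tif --out cal.json
thermoroi.R quantify  --roi roi.json --cal cal.json --out heat.json
thermoroi.R study     --table subjects.csv --out summary.json
```

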