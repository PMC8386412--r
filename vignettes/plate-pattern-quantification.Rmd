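---
title: "Quantifying radial growth patterns on agar plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial growth patterns on agar plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscan)
```

## The measurement problem

When a colony of public-good producers (for example, invertase-secreting
yeast) is spotted at the center of a lawn of non-producing "cheater"
cells on sucrose plates, the plate develops a characteristic radial
pattern after several days: a bright central **spot** of producer
growth, a dark annular **valley** where lawn growth is inhibited
(the producers act as a sink for other limiting nutrients), and a dense
bright **ring** of cheater growth further out, where cells enjoy
diffusing hexose without the nutrient competition. The biology of
interest lives in the radii of these features — how far the inhibition
zone extends, where the dense ring ends — measured in millimeters.

The raw data are ordinary photographs: consumer cameras, gel imagers,
phones. They carry glare, labels, uneven illumination and noise, which is
why a single radial intensity trace (or even the angle-averaged one) is
an unreliable basis for feature calls. This package implements a
bootstrap-consensus procedure that makes the feature localization robust
to angularly localized artifacts.

## The procedure

For one image, `quantify_plate()` performs:

1. **Rough spot detection.** A gradient-direction circular Hough
   transform finds the brightest circular blob in a configurable radius
   range. The detection only needs to be rough (a few pixels of center
   error are tolerated downstream, where the radial profile itself
   refines all feature radii). If no circle clears the interior-contrast
   score floor, a fallback takes the intensity-weighted centroid of
   pixels above the 95th percentile and refines it locally (see
   *Numerical choices*).
2. **Plate rim detection and calibration.** The same Hough machinery,
   searched over large radii, finds the plate's outer edge. Petri plates
   of this assay are 100 mm across, so a rim of radius $R$ px fixes the
   scale $\mathrm{mm/px} = 100 / (2R)$. A `mm_per_px` config override
   bypasses this when the rim is not visible.
3. **Polar transform.** The image is resampled around the spot center
   onto a radius-by-angle grid (default: 360 angular slices, 1 px radial
   bins, bilinear interpolation). Each column is one *angular slice*
   through the plate. Profiling stops at 92% of the rim radius so the
   rim's own intensity drop never masquerades as a growth feature.
4. **Bootstrap replicates.** For each of $B$ replicates (default 500),
   the angular slices are resampled with replacement into a *composite*
   polar image; the composite's radial profile is the per-radius
   **median** over its slices. The median is what buys artifact
   robustness: a glare sector corrupting a minority of slices leaves the
   median untouched, and the resampling turns "which slices did we
   trust" into a distribution instead of a single choice.
5. **Feature extraction per replicate.** The profile is smoothed
   (moving average, default window 11 bins) and differentiated (central
   differences). Feature bounds are sequential derivative extrema:
   the spot edge is the steepest descent within 1.5x the rough spot
   radius; the valley's inner bound is the next derivative minimum; its
   outer bound (equivalently the ring's inner bound) the next maximum;
   the ring's outer bound the next minimum. Extrema that do not clear
   the noise floor (below) are recorded absent.
6. **Consensus.** Across replicates, each feature's candidate radii form
   a distribution; the consensus radius is the mode (histogram with
   1-bin width, ties toward the smaller radius). A feature is reported
   only if it was found in at least `support_floor` (default 20%) of
   replicates. Radii convert to millimeters via the calibration.

`clockscan_profile()` separately provides the classic angle-averaged
radial intensity trace used for strain-to-strain comparison plots
(`plot_profiles()`).

## When is a feature real? (the absence rule)

Control plates — no producer spotted, or producers that cannot shape the
lawn — must come out "absent", so the acceptance threshold for a
derivative extremum matters as much as its localization. Three stacked
rules decide it; all three are config knobs:

* **MAD-anchored statistical floor.** `noise_floor_k` (default 4) times
  the Gaussian-consistent MAD of the derivative over the outer
  background annulus (outermost `background_frac` = 15% of bins), which
  on a correctly cropped plate holds only featureless lawn. Because an
  annulus of radius $r$ contains only about $2\pi r$ distinct pixels,
  the median profile is noisier near the center than at the rim; the
  tail-anchored floor is therefore scaled per radius by
  $\sqrt{\min(2\pi r_\text{tail}, n_\text{angles}) / \min(2\pi r,
  n_\text{angles})}$ (`noise_floor_profile()`). A flat floor
  demonstrably under-thresholds inner radii.
* **Effect-size floor.** Statistical floors cannot reject *systematic*
  intensity structure (illumination ripple survives any number of
  angular samples, and the background MAD scales with it). `min_step`
  (default 0.02, i.e. 2% of the dynamic range) is the smallest intensity
  step that counts as biology; through a moving average of width $w$ a
  step of height $\Delta$ peaks at $\Delta / w$ in the derivative, so
  the derivative floor is at least `min_step / w`. In simulation this is
  the rule that makes dark-control and no-valley plates come out clean
  even under a 5% illumination tilt with zero pixel noise.
* **Resolution guard.** Within half a smoothing window of a real edge
  the derivative carries that edge's own residual, so an extremum of
  *opposite* sign found there is not a distinct feature; the sequential
  search skips one filter support after each sign change. Same-sign
  searches are not guarded: in the canonical pattern the spot edge and
  the valley's inner bound share one transition.

The valley's two bounds are accepted or rejected as a pair, and the
radial ordering `spot <= valley_inner < valley_outer <= ring_outer` is
enforced on the consensus (the lower-support feature yields on
conflict).

## Tunable parameters

| key | default | units | meaning |
|---|---|---|---|
| `n_angles` | 360 | slices | angular resolution (1 per degree) |
| `radial_step` | 1 | px | radial bin width |
| `smooth_window` | 11 | bins | profile filter width (odd; clamped to length/4 on short profiles) |
| `smooth_method` | moving_average | — | or `savitzky_golay` (order 2) |
| `B` | 500 | replicates | bootstrap size ("hundreds"); `B = 1` disables resampling |
| `support_floor` | 0.2 | fraction | minimum replicate support |
| `noise_floor_k` | 4 | MADs | statistical floor multiplier |
| `background_frac` | 0.15 | fraction | outer bins treated as background |
| `min_step` | 0.02 | intensity | effect-size cutoff |
| `bin_width` | 1 | bins | consensus histogram bin |
| `plate_diameter_mm` | 100 | mm | physical plate size |
| `r_max_frac` | 0.92 | fraction | profiled fraction of the rim radius |
| `preprocess` | none | — | optional `contrast_stretch` (1st/99th pct); whether original photographs were contrast-adjusted is unknown, so this is off by default and recorded |
| `seed` | 1 | — | RNG seed; results are a pure function of (image, config, seed) |

## The synthetic-data generator

`synthetic_truth()` + `generate_plate()` render plates with known ground
truth: a radial step function over off-plate / lawn / ring / valley /
spot intensity levels whose transitions are Gaussian-blurred sigmoids
(`pnorm`; exact steps at zero blur), plus a linear illumination tilt,
i.i.d. additive Gaussian noise clipped to [0, 1], and angular occlusion
sectors stamped to the lawn level last (saturating glare carries no
noise). The default geometry mirrors the qualitative spot / valley /
ring layout of a producer spotted on a cheater lawn: 3 mm spot, valley
from 3 to 9 mm, ring out to 20 mm on a 100 mm plate rendered at 230 px
rim radius in a 512 px frame; intensity levels (0.9 spot, 0.15 valley,
0.75 ring over a 0.35 lawn) are presets chosen to resemble such
photographs, not measurements. Additive Gaussian noise was chosen over
Poisson because the inputs are consumer-camera photographs, not
photon-counting data.

What a green test on synthetic plates does establish: correct geometry
and calibration, correct profile statistics, robustness to the modeled
artifact classes (noise, tilt, pie-sector occlusions, center offset),
and correct absence calls on pattern-free controls. What it does not:
robustness to artifact classes the generator does not model — colony
granularity and texture, lens distortion, non-circular plates,
reflections with internal structure, condensation. The generator states
a world; real plates are messier.

## Numerical choices

* **Tie-breaks are deterministic everywhere.** Hough: highest vote
  count, ties toward smaller radius, then array order. Extremum scans:
  first index. Consensus mode: smaller radius. This makes results
  byte-reproducible across runs and platforms.
* **Hough pre-smoothing.** The gradient is taken on a Gaussian-smoothed
  copy (sigma 2 px); without it the edge map of a noisy photograph is
  mostly noise. Edge pixels are the top 5% of gradient magnitudes for
  the spot and the top 15% for the rim — on a patterned plate the rim
  is often the *weakest* edge and must stay in the map.
* **Fallback center refinement.** The global bright-pixel centroid is
  easily skewed by glare and tilt (several px). Two refinement passes
  recompute the centroid from pixels within 1.5x the current radius that
  exceed the spot/background midpoint; center error then stays near one
  pixel, which matters because a center offset shifts all consensus
  radii coherently.
* **Boundary handling.** Profile smoothing uses reflect padding (no
  spurious edge derivatives at r = 0 or r_max); the derivative uses
  one-sided differences at the two ends; out-of-frame polar annuli are
  truncated (and the truncation radius recorded) rather than zero-filled,
  which would fabricate a dark ring.
* **Degenerate inputs.** Constant profiles yield no features (a 1e-8
  derivative guard absorbs float dust where the MAD floor is exactly
  zero); profiles too short for the configured window fall back to the
  widest valid window; featureless plates route through the centroid
  fallback and report all features absent rather than failing.
* **RNG discipline.** One generator stream, seeded from the config,
  consumed sequentially across replicates; the caller's RNG state is
  saved and restored, so quantification never perturbs a user's session
  randomness.

## Design choices where the ground was open

* **Circle finding** is a gradient-direction circular Hough transform
  with integer vote counts — standard, deterministic, and easy to
  reproduce exactly in an independent reference implementation.
* **How many slices per composite** is the classical reading of a
  bootstrap: `n_angles` draws with replacement from the `n_angles`
  slices.
* **The ring's bounds** are defined by sharing: ring_inner is
  valley_outer (the valley sits immediately inside the dense ring), and
  ring_outer is the next derivative minimum — the valley-bound rule
  extended symmetrically outward.
* **B = 500** sits mid-range of "hundreds"; tests use 10–200 for speed,
  and the noise-free limit (`B = 1` equals any `B`) guarantees the
  bootstrap adds nothing when slices agree.

## Known limitations

* One plate per image; multi-plate photographs need prior cropping.
* No lens-distortion or vignetting correction; a strong radial
  vignette would bias the profile systematically.
* The sequential extremum scan assumes the canonical spot-valley-ring
  ordering; concentric multi-ring patterns beyond one valley/ring pair
  are not segmented.
* Features narrower than the smoothing window are flattened; lower
  `smooth_window` (or switch to Savitzky-Golay) for fine patterns, at
  the cost of a higher effective noise floor.
* TIFF support covers baseline uncompressed files only (the common
  scientific-camera export); LZW-compressed or tiled TIFFs are rejected
  with a clear message — convert externally.
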