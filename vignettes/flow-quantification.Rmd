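---
title: "Quantifying distal blood flow direction and velocity from dynamic CTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying distal blood flow direction and velocity from dynamic CTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowtrace)
```

## The problem

After an acute ischemic stroke, an occluding thrombus in the middle
cerebral artery (MCA) blocks the main supply route to downstream brain
tissue. What happens distal to the clot is clinically decisive and highly
variable: a permeable thrombus can still let some contrast (and blood)
through anterogradely, while leptomeningeal collaterals can fill the distal
branches retrogradely, toward the occlusion. Time-resolved CT angiography
(dynamic CTA, a 4D series of contrast-enhanced CT volumes) captures the
contrast bolus transit through these vessels, and the direction and speed
of that transit can be read out per branch.

`flowtrace` quantifies this: for each arterial branch of interest, distal
to a marked thrombus, it estimates the signed average contrast velocity and
classifies the case into one of three distal-flow patterns:

* **Pattern I** — all daughter branches anterograde,
* **Pattern II** — all daughter branches retrograde,
* **Pattern III** — both directions present.

## The measurement model

Every voxel on a vessel centerline has a time attenuation curve (TAC):
attenuation in Hounsfield units sampled once per frame interval
$\Delta t$ (typically 2 s, 30 frames). As the bolus advances along a
branch at average speed $v$, the TAC at arc-length $s$ from a reference
point is, to first order, a time-shifted copy of the reference TAC with
delay

$$\tau(s) = \tau_0 + s / v .$$

The pipeline therefore estimates, for every centerline voxel, the delay of
its TAC relative to the most proximal marker's TAC by normalized
cross-correlation, and regresses delay on arc-length per vessel segment.
The fitted slope is $1/v$; its sign is the flow direction (delay
increasing with distance = anterograde; decreasing = retrograde, i.e.
collateral filling from beyond).

Key assumptions, all inherited from the transport picture above:

* the bolus shape is approximately conserved along a segment (dispersion
  only attenuates the correlation peak, it does not bias a symmetric
  estimator);
* a single average velocity per segment is meaningful — branches are
  split at bifurcations precisely so that this holds piecewise;
* the contrast tracks the blood plasma; it does not prove that red blood
  cells traverse a permeable thrombus.

## Pipeline stages and the parameters that matter

1. **Registration** (`register_frames`, off by default): translation-only
   alignment to a reference frame by exhaustive integer-voxel search
   maximizing Pearson correlation (default ±3 voxels). A shift is applied
   only when it improves the correlation by at least `min_gain` (0.05) and
   the best correlation reaches `min_cor` (0.2): frames that share no
   structure with the reference (pre-bolus, essentially noise) would
   otherwise be dragged to a spurious correlation maximum. Clinical data
   registered upstream (e.g. with a full rigid registration) should skip
   this stage; sub-voxel motion is not corrected.
2. **Denoising** (`bilateral_denoise`): bilateral filter, spatial sigma one
   voxel, range sigma 30 HU by default. The range term preserves the
   vessel/tissue edges that both segmentation and path finding rely on;
   with an infinite range sigma the filter reduces to truncated-Gaussian
   smoothing (a property the test suite checks).
3. **t-MIP** (`compute_tmip`): voxelwise temporal maximum; vessels appear
   at peak enhancement. Everything geometric downstream depends only on
   the t-MIP, so results are invariant to frame reordering.
4. **Segmentation** (`segment_vessels`): thresholding of the t-MIP
   (absolute HU or percentile) with a minimum component size (10 voxels),
   or a user-supplied mask. Thresholding deliberately replaces learned
   segmentation: the scientific content of this package is the flow
   quantification, which only needs a mask covering the branches of
   interest, and an externally produced mask is a first-class input.
5. **Skeletonization** (`skeletonize`): distance-ordered homotopic
   thinning (implemented in C++). Border voxels are deleted in increasing
   chamfer-distance order only if deletion preserves the 26-connected
   foreground / 6-connected background topology and the voxel is not a
   curve endpoint; connected-component count is therefore preserved
   exactly. Skeleton twigs shorter than `spur_mm` (3 mm) ending in a free
   endpoint are pruned: they are thinning artifacts of surface bumps and
   would otherwise create spurious branch nodes.
6. **Path finding** (`min_cost_path`, `assemble_paths`): the centerline
   graph connects 26-adjacent skeleton voxels with anisotropic mm edge
   lengths. The route from each marker to the next minimizes
   $\sum \text{length}_{mm} \cdot (I_{max} - \bar I + \varepsilon)$, where
   $\bar I$ is the mean t-MIP intensity of the edge's endpoints, $I_{max}$
   the t-MIP maximum over the mask and $\varepsilon = 1$ HU a guard that
   keeps costs positive. This length-weighted form is scale-free in HU
   offset and penalizes detours. Ties between equal-cost routes are broken
   toward the lexicographically smallest voxel index, so paths are fully
   deterministic. Markers snap to the nearest skeleton node within 3
   voxels (Euclidean distance in mm; ties to the lowest index). Distal
   legs are partitioned where the per-branch paths diverge: the run shared
   by all paths is the *mother* segment, each divergent run a *daughter*.
   A single distal branch with no bifurcation is one daughter, so that
   classification always has daughters to vote on.
7. **TAC conditioning** (`condition_tac`): baseline subtraction, temporal
   upsampling by 10 (2 s to 0.2 s grid) via cubic spline interpolation,
   then a zero-phase (forward–backward) Butterworth low-pass, order 4,
   cutoff 0.1 Hz. Zero phase is non-negotiable — a causal filter's group
   delay would masquerade as flow delay; the suite verifies that
   conditioning two exact shifted copies moves their estimated relative
   delay by well under 0.1 s. The spline (rather than Fourier or polyphase
   band-limited interpolation) was chosen because bolus records are short
   and non-periodic: spectral methods ring at the record edges, while the
   bolus's sub-0.05 Hz content is so heavily oversampled at the native
   0.25 Hz Nyquist that spline interpolation is shift-consistent to far
   below the delay-error budget. The baseline is the mean of the native
   frames before the curve first rises above 10% of its range — the
   practical reading of "pre-arrival frames" for curves whose arrival is
   not yet known.
8. **QC** (`qc_discard`): TACs whose conditioned maximum is below 5% of
   the proximal reference maximum are discarded (strictly below — exactly
   5% is kept). The comparison uses conditioned maxima for noise
   robustness; the choice is recorded in the delays output.
9. **Delay estimation** (`xcorr_delay`): normalized (Pearson)
   cross-correlation over the overlapping support, lag search within half
   the record duration, peak refined to sub-sample precision by quadratic
   interpolation through the peak and its neighbours; exact ties resolve
   to the smallest absolute lag. Normalization makes the delay invariant
   to amplitude scaling — important where a permeable thrombus attenuates
   enhancement without changing timing.
10. **Velocity fits** (`fit_segment_velocity`): ordinary least squares of
    delay on arc-length per segment (Theil–Sen available for
    outlier-heavy profiles); `velocity = 1/slope`, signed. Segments with
    fewer than 3 valid points are unresolved. A direction dead-band
    `slope_min = 0.005` s/mm (|v| > 200 mm/s) reports near-flat profiles
    as unresolved: with 2 s frames over at most ~100 mm of path, shallower
    slopes sit below the temporal quantization floor and their sign is
    noise. This mirrors the flat, zero-delay profiles seen in fast-flow
    branches, where contrast appearance cannot be timed at the scanner's
    frame interval.
11. **Classification** (`classify_pattern`): the resolved daughter
    directions vote; the mother segment and unresolved daughters do not.
    No resolved daughters yields "indeterminate" rather than an error.

## The phantom: what it emulates and what it does not

Patient dynamic CTA cannot be redistributed, so the package ships a
bolus-transport phantom (`phantom_spec`, `render_dynamic`) that generates
4D volumes with exact ground truth. A vascular tree is a set of straight
tubes (each at least one voxel spacing in radius, connected into a tree);
contrast arrival propagates along each tube at a prescribed signed
velocity, so the ground-truth delay slope per segment is exactly
$1/v$ — the oracle for parameter recovery. The bolus is a gamma-variate,

$$C(\tau) = A\,(\tau/t_p)^{\alpha} e^{\alpha (1 - \tau/t_p)},$$

the standard first-pass model, with defaults $A = 400$ HU, $t_p = 6$ s,
$\alpha = 3$ — plausible cerebral-CTA values chosen once, not fitted to
any data set. Noise is additive i.i.d. Gaussian (default 10 HU) from a
private, seeded RNG stream, so renders are bit-reproducible. Retrograde
segments receive contrast at their distal end (emulating collateral
filling); a thrombus is a tube sub-interval whose enhancement is scaled by
a permeability factor in [0, 1]. Default sampling mirrors clinical
acquisition, 2 s frames and 30 time points, at reduced grid size.

Deliberately absent: hemodynamics (no pressure-driven flow), X-ray physics
(no beam hardening or photon noise), partial-volume blur (binary tube
membership keeps the ground truth exact), bolus dispersion, cardiac
pulsatility, and patient motion. Passing the phantom tests therefore
demonstrates the estimator's correctness under the transport model — not
robustness to dispersion, pulsatility or segmentation failure on clinical
scans.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based inside R; marker JSON files and exported CSVs
  use 0-based indices, converted at the interface.
* World coordinates are `origin + (index - 1) * spacing`; frame `k` occurs
  at `(k - 1) * dt` s. All distances are computed with anisotropic
  spacing.
* Constant (structureless) frames register with zero shift and a warning;
  zero-variance TACs produce invalid delay points, not errors; empty
  masks, unreachable markers and disconnected path endpoints fail with
  explicit messages naming the offending input.
* The cross-correlation's quadratic refinement is only applied when the
  peak is interior and concave, and is clamped to half a lag step.
* Two renders, runs, or pipeline invocations with the same configuration
  and seed produce byte-identical outputs.

## Problem sizes in the test suite

The suite exercises the full pipeline at desk scale, chosen so every
property is still sharply testable: straight-tube phantoms of
60 × 9 × 9 voxels (50 mm tubes, velocities 2–20 mm/s in both directions,
30 frames at 2 s), Y-shaped trees of 40 × 40 × 17 voxels with ±5 mm/s
daughters, 500 TAC pairs for the temporal-quantization bound, 100 random
20³-grid instances for the shortest-path oracle comparison, and 50 seeded
noisy runs for direction robustness at 10 HU noise on 400 HU enhancement.
An independent Bellman–Ford relaxation, a dense 0.01 s-grid
cross-correlation, and brute-force temporal maxima serve as oracles.

## Known limitations

* With 2 s frames, a single-voxel delay estimate carries up to ~1 s of
  quantization error at native lag resolution; velocities above the
  dead-band limit are reported as unresolved rather than guessed.
* The linear delay–distance fit is an average; real distal branches show
  locally varying velocities, and side branches not captured by the
  markers can make flow appear non-conserved.
* Thresholding segmentation requires well-enhanced vessels; for clinical
  data a dedicated segmentation should be supplied as a mask.
* Translation-only registration cannot correct rotational head motion.
* Branch selection is the user's: markers determine the analyzed
  topology, including which leg counts as the thrombus leg.
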