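# flowtrace

Distal blood-flow direction and velocity from 4D dynamic CT angiography.

After an acute ischemic stroke, the tissue fate distal to the occluding
thrombus depends on where its residual blood supply comes from: anterograde
leakage through a permeable thrombus, retrograde filling by leptomeningeal
collaterals, or both. `flowtrace` measures this from time-resolved CTA: it
traces vessel centerlines distal to a marked occlusion, times the contrast
bolus at every centerline voxel, and turns delay-versus-distance profiles
into signed per-branch velocities and a distal flow-pattern classification.
It is aimed at neurovascular imaging researchers working with dynamic CTA
(CT-perfusion source) data.

## Method

For a voxel at arc-length *s* along a branch carrying contrast at average
velocity *v*, the time attenuation curve (TAC) is a delayed copy of the
proximal reference TAC with delay

    tau(s) = tau0 + s / v .

The pipeline:

1. temporal maximum intensity projection (t-MIP) of the aligned, denoised
   4D volume;
2. vessel mask by t-MIP thresholding (or supplied), skeletonized by
   topology-preserving 3-D thinning to a centerline graph;
3. marker-guided minimum-cost paths (proximal → thrombus → each distal
   branch) through the skeleton, where bright t-MIP voxels are cheap;
   distal legs are split into mother/daughter segments at bifurcations;
4. per-voxel delays relative to the most proximal marker by normalized
   cross-correlation of interpolated, zero-phase low-pass-filtered TACs,
   with a 5% amplitude quality-control discard;
5. ordinary least-squares fit of delay on arc-length per segment —
   the slope's inverse is the signed velocity (mm/s), its sign the
   direction (positive/increasing delay = anterograde);
6. classification: all daughters anterograde → Pattern I, all retrograde →
   Pattern II, mixed → Pattern III.

A synthetic bolus-transport phantom (gamma-variate bolus propagating along
tubular trees at prescribed signed velocities) provides 4D volumes with
exact ground truth for every stage.

## Worked example

Three phantom scenarios are bundled; each renders a Y-shaped arterial tree
(proximal trunk, permeable-thrombus interval, mother segment, two
daughters) and runs the full pipeline:

```r
library(flowtrace)
cfg <- system.file("extdata/pattern3_config.json", package = "flowtrace")
res <- run_pipeline(cfg, output_dir = "out_pattern3")
res$pattern
#> <flow_pattern> Pattern III
#>   1/daughter2: anterograde, v = 5.28 mm/s (n = 10, R^2 = 0.997)
#>   2/daughter1: retrograde, v = -5.34 mm/s (n = 10, R^2 = 0.999)
```

The phantom's daughters carry contrast at +5 and −5 mm/s; the recovered
velocities (+5.28, −5.34 mm/s) agree to within the discretization of a
2 s frame interval on a 1 mm grid, and the mixed directions give
Pattern III. `out_pattern3/` contains the centerline paths and per-voxel
delays (CSV), the per-segment fits and pattern (JSON), and a manifest of
every parameter used. The same run from a shell:

```sh
Rscript inst/cli/flowtrace.R run --config inst/extdata/pattern3_config.json --out out_pattern3
```

For clinical-style input, point the configuration's `input` block at a 4D
NIfTI volume (frame interval in the header or a JSON sidecar), an optional
mask/ROI, and a markers JSON with 0-based voxel indices for the proximal,
thrombus and distal reference points.

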