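# otoct

Noise reduction and automatic segmentation for osmium-tetroxide (OsO₄)
contrast-enhanced micro-CT volumes of the human inner ear.

OsO₄ staining binds unsaturated lipids, so myelinated neural tissue —
cochlear and vestibular nerve fibers, the spiral ganglion — appears
hyperdense inside the less radiodense decalcified bone of the labyrinth.
Visualizing that micro-anatomy in 3D requires removing sensor noise and
isolating the bright neural compartment from the surrounding bone and
membranes with as little manual work as possible. `otoct` implements two
processing chains for this, as fully 3D operators over normalized
intensity volumes, plus a synthetic phantom generator so every stage can be
validated quantitatively without any scan data. It is intended for
researchers processing contrast-enhanced micro-CT reconstructions of
temporal bones (or similar stained specimens) ahead of volume rendering in
external tools such as 3D Slicer.

## The two chains

**2D-visualization denoising** (`run_pipeline_2d`), for slice viewing:

1. *Histogram matching*: every z-slice is remapped through the monotone map
   F⁻¹_ref ∘ F_k (empirical quantile mapping) onto a chosen reference
   slice, equalizing contrast along the scan axis.
2. *Iterated edge-preserving smoothing*: 4 repeats of the triplet
   (guided filter, bilateral filter, guided filter) — 12 nonlinear filter
   applications. The self-guided filter solves per 3×3×3 window
   a_k = v_k/(v_k + ε), b_k = (1 − a_k)·m_k and outputs q = Ā·I + B̄ with
   r = 1, ε = 1; the bilateral filter weights neighbors by
   G_σ(‖x − y‖)·exp(−(I(x) − I(y))²/(2μ)) with σ = 1 voxel, μ = 0.00017
   (range variance in normalized units).
3. *Unsharp masking*: q = clip(I + α(I − G(I))) to counteract smoothing
   blur.

**3D-visualization denoising + automatic segmentation**
(`run_pipeline_3d`), for volume rendering:

1. Guided filter (r = 1, ε = 1).
2. *White top-hat* with a 3D cross structuring element of radius 64
   (`I − opening(I)`): keeps bright structures that cannot contain all
   three 129-voxel arms — thin nerves, membranes — and suppresses broad
   bone.
3. *Binarize* at the absolute threshold 0.035 (intensities are normalized
   by the sample-type maximum, 65535 for 16-bit, so the threshold has a
   fixed physical meaning).
4. *Geodesic opening* of size 15: erosion by a 31³ box followed by
   morphological reconstruction — connected components that cannot contain
   a 31³ box (small unconnected noise objects) are deleted entirely;
   survivors are restored voxel-identically.
5. *Closing* (box, size 2) and *dilation* (cross, radius 1) pad the mask.
6. *Image multiply*: the top-hat volume times the mask is the render-ready
   segmented output. An optional manual mask is intersected (logical AND)
   to exclude circumjacent structures.

Erosion and dilation use van Herk/Gil-Werman line decompositions, so
runtime is independent of the structuring-element radius.

## Worked example

```r
library(otoct)

ph  <- generate_phantom(phantom_spec())       # 160^3 synthetic inner ear
run <- run_pipeline_3d(ph$volume, pipeline_config())
print(run)
score_segmentation(run$mask, ph$truth, "nerve", boundary_tolerance = 1)
surviving_components(run$mask, ph$truth, "speckle")
```

prints

```
<otoct 3D segmentation run>
  8 stages, 9.18 s total
  final mask: 328003 foreground voxels (8.008%)
<segmentation_score> dice 0.8770 | precision 0.7809 | recall 1.0000
  TP 235613, FP 66120, FN 0 (boundary tolerance 1 voxel)
  truth components detected: 1 / 1; false components: 0
[1] 0
```

The phantom's nerve compartment (a ganglion trunk with 20 fibers fanning
out along a helix) is recovered with Dice 0.877 against ground truth — the
recall of 1.0 means no nerve voxel is lost, and the precision below 1
reflects the mask padding that the closing/dilation steps intentionally
add. All 60 injected speckle-noise blobs are deleted (`0` surviving
components), and the single nerve component survives intact.

Volumes are read and written with `read_volume` / `write_volume`
(multi-page or per-slice TIFF stacks, NRRD, NIfTI-1; axis order `(z, y, x)`
with z the stack axis), and a shell interface is installed at
`system.file("cli", "otoct", package = "otoct")` with subcommands
`phantom`, `denoise2d`, `segment3d` and `eval`.

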