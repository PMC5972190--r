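---
title: "Denoising and automatic segmentation of contrast-enhanced micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising and automatic segmentation of contrast-enhanced micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoct)
```

## The problem

Osmium tetroxide staining makes myelinated neural tissue hyperdense in
micro-CT scans of decalcified temporal bones: nerve fibers, ganglia and
membranes of the inner ear become bright structures inside darker spongy
bone. Two obstacles stand between a raw reconstruction and a useful 3D
rendering: sensor noise (including slice-to-slice intensity drift along
the scan axis) and the fact that ray-cast rendering of the whole volume
buries the thin neural structures inside everything else that is even
moderately radiodense. `otoct` addresses both with a denoising chain for
2D slice viewing and a denoising + automatic segmentation chain for 3D
rendering, operating on normalized intensity volumes in `[0, 1]` with axis
order `(z, y, x)`.

Normalization divides integer samples by their type maximum (65535 for
16-bit) rather than by the observed maximum. This is deliberate: the 3D
chain binarizes at an *absolute* threshold, and per-volume rescaling would
silently change what that threshold selects.

## The 2D chain

`run_pipeline_2d` applies, in order:

1. **Per-slice histogram matching** (`histogram_match_slices`). Every
   z-slice is remapped through the monotone map `F_ref^-1 o F_k`, built by
   empirical quantile mapping with 1024 interpolation knots (configurable;
   exact per-value mapping is approached as the knot count grows). The
   reference slice defaults to the middle slice — the choice is a free
   parameter of the protocol, and the middle slice is simply the one most
   representative of the stack under slow axial drift. A constant
   reference slice makes the map undefined and is an error, with one
   exception: a fully constant volume already matches its reference and
   passes through unchanged. Matching is applied once, before the filter
   iterations.
2. **Iterated edge-preserving smoothing**: `block_iterations = 4` repeats
   of the triplet (guided, bilateral, guided), i.e. 12 nonlinear filter
   applications. The count of twelve is a fixed property of the protocol;
   whether it counts individual filter applications or triplet repeats is
   genuinely ambiguous, so the interpretation is configurable —
   `block_iterations = 4` (the default reading, 12 applications) or 12.
3. **Unsharp masking** (`sharpen`): `q = clip(I + amount * (I - G(I)))`,
   Gaussian `G` with `blur_sigma = 1` voxel and `amount = 1`. The
   sharpening step of the protocol carries no parameters, so these
   defaults are declared assumptions, exposed in the configuration.

### Filter definitions and their parameters

Both smoothers are fully 3D (cubic windows) and reflect-pad their borders
— replication would be equally defensible, but reflection avoids biasing
the local variance estimates at the faces; the convention is fixed and
recorded in the configuration echo.

* **Guided filter** (`guided_filter`, self-guided): per cubic window
  `w_k` of half-width `r`, `a_k = v_k / (v_k + eps)`,
  `b_k = (1 - a_k) m_k` from the window mean and variance, output
  `q = A I + B` with `A`, `B` box means of the coefficients. With
  normalized data the variance is at most 0.25, so `eps = 1` forces
  `a_k <= 0.2`: the filter acts nearly as a box mean on flat noise while
  retaining a fraction of strong edges. `r` and `eps` are dimensionless
  (voxels / squared normalized intensity).
* **Bilateral filter** (`bilateral_filter`): spatial Gaussian of standard
  deviation `sigma = 1` voxel, range kernel `exp(-dI^2 / (2 mu))`. `mu`
  is read as the *variance* of the range kernel: `mu = 0.00017`
  corresponds to a range standard deviation of about 0.013 in normalized
  units, i.e. about 860 gray levels of a 16-bit volume — consistent with
  the normalize-by-type-maximum convention above. The kernel is truncated
  at `ceiling(2 sigma)` voxels; as `mu` grows the filter provably
  converges to a plain truncated Gaussian blur, which the test suite
  checks.

## The 3D chain

`run_pipeline_3d` applies guided filtering, then:

1. **White top-hat** (`white_tophat`) with a 3D *cross* structuring
   element of radius 64 — the union of three axis-aligned 129-voxel
   segments, the 3D analogue of a 2D cross matrix. The opening it
   subtracts can only preserve bright regions that contain a translate of
   all three arms; nerves, membranes and other thin structures cannot, so
   they survive in the residual near their original contrast while broad
   bone is suppressed to near zero.
2. **Binarization** at 0.035, ties-as-foreground (`>=`). The boundary
   convention at exactly the threshold is not prescribed anywhere, so it
   is a declared decision.
3. **Geodesic opening** of size 15: the mask is eroded by a box of
   half-width 15 and the surviving marker is reconstructed by geodesic
   dilation under the original mask. Equivalently — and this is how it is
   computed — a connected component is kept voxel-identically iff it
   contains at least one voxel of the eroded marker; all other components
   are removed entirely. Reconstruction connectivity defaults to 26 so
   that thin diagonal fiber paths stay connected; it is configurable to 6.
4. **Closing** (box, half-width 2) and **dilation** (cross, radius 1) pad
   the mask so delicate structures are fully enclosed. The closing and
   geodesic sizes are printed without shapes in the protocol; box
   elements are used because integer-radius morphology conventionally
   means full ranges, while the cross shape is used exactly where a cross
   matrix is named.
5. **Masked multiplication**: the segmented output is the *top-hat*
   volume times the final mask — the mask is applied to the processed
   volume, not the raw input. A manual mask, when supplied, is
   intersected (AND) with the automatic mask: manual segmentation in this
   workflow *excludes* circumjacent structures, it never adds voxels.

### Numerical and implementation choices

* Grayscale morphology pads by edge replication; binary morphology pads
  with background (0), so mask components touching a volume face erode
  from that side. Both conventions are documented and testable; the
  duality `erode(v) = 1 - dilate(1 - v)` holds away from faces.
* Erosion/dilation along lines use the van Herk/Gil-Werman running
  min/max, O(1) per voxel in the radius; cross elements are the pointwise
  min/max of three line passes and are bit-identical to direct offset
  enumeration (a property the suite asserts for radii 1, 2, 3 and 64).
  This is what makes the radius-64 top-hat affordable.
* Both chains are deterministic: rerunning with the same input and
  configuration is bit-identical, and the echoed YAML configuration plus
  the per-stage report (durations, output statistics) written by
  `save_run` reproduce any run exactly.
* Degenerate inputs: structuring elements larger than the smallest axis
  warn and degenerate toward a constant rather than erroring; an all-zero
  volume yields an empty mask and a zero segmented volume.

## The phantom: what it emulates and what it does not

`generate_phantom` builds a seeded synthetic inner ear with voxel-level
ground truth (labels background / bone / membrane / nerve / speckle,
recorded *before* blur and noise):

* a bright solid **trunk** (the modiolus/ganglion compartment, mean
  intensity 0.55) that admits an inscribed 31³ box, so the geodesic
  opening must preserve the whole nerve component;
* 20 thin **fibers** (radius 2.5 voxels) fanning out of the trunk along a
  helix whose radial reach decreases toward the apex, keeping the nerve a
  single connected component;
* a thin **membranous shell** (0.25) and a surrounding **bone annulus**
  (0.15) whose geometry cannot contain a 31³ box anywhere, so both must
  be deleted by the geodesic opening even though they binarize as
  foreground;
* 60 isolated **speckle** blobs (radius 1–3, intensity 0.55) placed with
  enough clearance that partial-volume blur cannot bridge them to any
  structure — all must vanish from the final mask;
* Gaussian partial-volume blur (σ = 0.7 voxel), a linear z-drift of 0.02
  peak-to-peak, and additive Gaussian noise (σ = 0.02), all clipped to
  `[0, 1]`.

The intensity ordering nerve > membrane > bone > background encodes the
contrast the stain provides; the absolute levels are plausible stand-ins
(no quantitative tissue statistics are available for stained specimens)
and are fully configurable, not claims about real data. The phantom does
*not* model beam hardening, blooming around hyperdense nerves, uneven
stain uptake, or anatomically exact cochlear geometry — all present in
real scans. Passing the phantom tests therefore demonstrates the
correctness and robustness of the operators and the chain logic, not
clinical-grade accuracy on real specimens.

Evaluation tolerates a one-voxel band around the truth boundary
(`score_segmentation`, `boundary_tolerance = 1`, always reported with the
score) because truth is assigned pre-blur while the chain sees the
blurred volume.

## Validation sizes and what the suite computes

The test suite validates the filters against brute-force per-window
oracles on 6³–9³ volumes (tolerances 1e-10 to 1e-8), morphology against
direct offset enumeration on 16³–48³ volumes (bit-identical), and the
chains end-to-end on a 160³ phantom and a 128³ flat noise block — sizes
chosen so a full run takes seconds to a couple of minutes on a single
core while still containing the radius-64 top-hat context and the 31³
geodesic criterion. On those inputs the 3D chain recovers the nerve with
Dice ≈ 0.88 at recall 1.0 (the padding steps intentionally cost
precision), deletes all 60 speckles, and the 2D chain reduces the noise
standard deviation in a flat region by ≈ 98%. `scripts/acceptance.R`
recomputes these quantities from scratch for any seed.

## Known limitations

* The geodesic opening is implemented for binary masks only (grayscale
  reconstruction is out of scope), and arbitrary user-supplied kernels
  beyond cross/box/ball are not supported.
* Volumes are processed in memory; multi-gigabyte scans need more RAM
  than a laptop typically offers, and out-of-core tiling is not
  attempted.
* TIFF files written here carry no voxel-spacing metadata; use NRRD or
  NIfTI when spacing matters downstream. Spacing is descriptive
  everywhere — all operators work in voxel units.
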