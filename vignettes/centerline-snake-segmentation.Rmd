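---
title: "Centerline-based segmentation of tubular anatomy with greedy active contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-based segmentation of tubular anatomy with greedy active contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vtseg)
```

## The problem and the model

Elongated, curved cavities — the vocal tract in volumetric MRI is the
motivating case, but vessels and similar lumina fit the same mould — are
awkward to segment as 3-D objects, yet their physiologically interesting
descriptor is one-dimensional: the cross-sectional area as a function of
distance along the lumen (for the vocal tract, the area function that
determines the acoustic transfer function and hence vowel formants). vtseg
therefore reduces the 3-D problem to a chain of 2-D ones:

1. **Centerline.** The operator places a handful of landmark nodes through
   the lumen on the midsagittal view; a piecewise cubic
   `c_i(t) = a3 t^3 + a2 t^2 + a1 t + a0`, `t ∈ [0,1]`, interpolates them
   with matched first derivatives at shared nodes (C1). Node tangents are
   Catmull–Rom finite differences `(P[i+1] − P[i−1])/2` (one-sided at the
   ends): the construction is local, needs no global solve, and is exactly
   reproducible. The price is that the two end segments, which only have a
   one-sided difference to work with, track a curved target less tightly
   than interior segments; landmarks should extend slightly past the region
   of interest.

2. **Cross-section resampling** (curved planar reformation). Frames are
   placed at fixed *arc-length* steps along the spline — stepping in the
   spline parameter would space slices unevenly wherever node spacing
   varies. Each frame is the Frenet triad: slice z-axis the unit tangent
   `t = c' / |c'|`, x-axis the unit binormal `b = c'×c'' / |c'×c''|`, and
   y-axis the *negated* unit normal `−n`, which absorbs the left-handed
   raster convention of image stacks while keeping the (x, y, z) triad
   right-handed. The 4×4 affine with columns `(b, −n, t, c)` maps in-plane
   mm coordinates to world mm; the stack is sampled trilinearly on a square
   grid in that plane.

   The binormal is undefined where the curve is locally straight
   (`|c'×c''| < 1e-8 |c'|^2`). There the frame is parallel-transported from
   its predecessor (a straight start with no predecessor uses a fixed
   arbitrary perpendicular), and after any degenerate run the binormal sign
   closest to the previous frame's x-axis is chosen. Without both rules a
   curvature inflection can flip the frame by 180° between adjacent slices,
   which would poison the inter-slice coupling below.

3. **Greedy active contour per slice.** A closed polygon of nodes `v_i`
   deforms by visiting nodes in order and moving each to the position in
   its 3×3 (configurable) window minimizing

   `E = α·|v_{i+1} − v_i|² + β·|v_{i+1} − 2v_i + v_{i−1}|² − γ·|∇I|² + δ·d⁴`

   with `d` the distance to the nearest node of the previous slice's
   contour (zero on the first slice). Iteration stops when a pass moves no
   node or after `max_iter = 30` passes. Node management keeps spacing
   within `[s_min, s_max] = [3, 12]` px (`s_max = 4 s_min`): over-long
   edges gain their midpoint, the second node of under-spaced pairs is
   deleted. Insertion and deletion alternate until both bounds hold,
   because a deletion can merge two short edges into one longer than
   `s_max`. Segmentation then walks the stack: each slice is initialized
   with — and coupled through `E_dev` to — its predecessor's result.

4. **Reconstruction.** Shoelace areas per contour give the area function;
   compartment volumes superpose slice areas (rectangle rule,
   `Σ area · step`; trapezoid optional); contours map back to world space
   through the frame affines; adjacent rings, resampled to a common vertex
   count and rotationally aligned for minimal twist, are stitched into a
   triangle mesh, optionally capped.

## Parameter choices that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | −1 | — | continuity weight; the term is a squared forward difference, so a *negative* weight makes minimization push nodes apart — the expansion drive |
| `beta` | 0.2 | — | bending stiffness |
| `gamma` | 2 | — | edge attraction (squared gradient magnitude) |
| `delta` | 1 | — | inter-slice coupling, `d` to the previous contour's nodes |
| `s_min`, `s_max` | 3, 12 | px | node-spacing bounds, `s_max = 4 s_min` |
| `max_iter` | 30 | passes | per-slice iteration cap |
| `window` | 3 | px | greedy search neighbourhood side |
| `step_mm` | 1.04 | mm | distance between cross-section centers |
| `pixel_size_mm` | 0.35 | mm | cross-section pixel size |
| diffusion `n_iter`, `kappa`, `step` | 10, 10, 1/7 | —, intensity, — | edge-preserving preprocessing |

Two design points deserve their own words, because the underlying
formulation leaves them genuinely open:

**The sign of the continuity term.** A squared first derivative, minimized,
*shrinks* a contour; yet the term is conventionally described as driving
expansion. We implement the term exactly as written and let the weight
carry the sign: `alpha < 0` turns minimization into expansion. The default
is `alpha = −1`. A related subtlety fixed `beta`: at coarse node spacing
the discrete curvature term points sharply inward (toward the chord
midpoint), and any `beta ≳ 0.3` makes the polygon collapse before the edge
can catch it; `beta = 0.2` preserves stiffness against noise without
overwhelming the expansion.

**Window-wise min–max normalization and its flat-window guard.** The four
energy terms have incommensurate scales (px² vs intensity²·px⁻²), so each
is min–max normalized over the search window before weighting — the
standard greedy-snake practice (raw mode is available via
`normalize = FALSE`). Normalization has a failure mode, though: deep inside
a featureless lumen the window's gradient range is pure sensor noise, and
stretching it to [0, 1] hands the edge term full weight for garbage,
pinning nodes to noise specks. The guard `flat_tol = 1e-3` treats a window
whose gradient range is below that fraction of the slice's maximum squared
gradient as flat (zero edge term), restoring clean expansion through
homogeneous regions.

Other numerical choices: trilinear interpolation everywhere; isotropic
rescaling uses the voxel-center convention with border replication (so a
constant stack stays constant and factor 1 is the identity), while
cross-section sampling outside the volume returns 0; greedy ties prefer the
current position, then the smallest offset, then row-major order, making
every stage bit-deterministic; arc-length positions are found by adaptive
Gauss–Kronrod quadrature (relative error < 1e-6) and inverted with
`uniroot` to 1e-10; the deviation distance uses the previous contour's
*vertices* (the literal rule), with point-to-segment mode available;
diffusion uses the exponential conductance `exp(−(∇I/κ)²)` on the
6-connected stencil, with the explicit step capped at 0.25.

On slice-count arithmetic: scaling a 52-slice stack of 1.04 mm pixels by
3.0 gives 156 slice images with 0.35 mm (1.04/3 mm) pixels; making the
volume truly isotropic at that pixel size turns the 93.6 mm through-plane
extent into 270 planes. `make_isotropic` does the latter in one resampling
step; `isotropy_report()` exposes both numbers.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds tube stacks with analytically known geometry:
straight, circular-arc, or arbitrary-spline centerlines; constant, linearly
tapering, or sinusoidal radius profiles; dark lumen in a bright wall (air
is dark in MRI; the snake uses gradient magnitude and is polarity-
agnostic); Gaussian border blur emulating partial-volume softening; and
seeded additive Gaussian noise. The reference conditions — a 128³ voxel
grid at 1 mm, an 8 mm tube on a 40 mm-curvature quarter arc, 0.5 mm blur,
noise at 5% of the lumen/wall contrast — exercise exactly the failure
modes that matter for this method: frame orientation on a curved path,
expansion against noise, and area recovery at finite resolution.

What the phantom does *not* emulate: Rician MRI noise statistics, motion
and phonation blurring, intensity inhomogeneity, anatomy that departs from
a locally convex tube (deep concavities, side recesses such as the
piriform sinuses), and teeth-like signal voids. Passing the phantom suite
therefore demonstrates the geometric and numerical correctness of the
pipeline and its behaviour under moderate noise — not segmentation quality
on clinical data, where the operator-facing escape hatches (contour
overrides standing in for manual correction, forbidden-region masks
standing in for teeth exclusion) exist precisely because a greedy local
optimizer cannot be trusted everywhere.

Typical accuracy under the reference conditions (seed 0): per-slice area
error ~5 mm² on a 201 mm² cross section with a worst slice near 10 mm²,
against the 1-pixel boundary uncertainty bound
`2 · perimeter · pixel_size ≈ 35 mm²`; total volume within ~2% (5% bound).
The dominant residual is not boundary placement but the inscribed-polygon
chord deficit: with `s_max = 12` px a circle of radius 23 px carries only
~20 nodes, and its polygon area sits 2–3% below the disk. Halving
`s_min`/`s_max` halves that bias at proportional cost.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
128³ reference phantom (61 cross sections of 97², about half a minute) and
smaller 40³–48³ cylinders for the I/O, propagation, and determinism
checks; property suites use seeded randomized cases. These sizes were
chosen to probe every code path at comfortable desk scale.

## Known limitations

- The greedy snake finds *local* energy minima; a seed far off-center in a
  strongly non-convex section can lock onto the wrong edge. Overrides and
  masks are the intended remedy, as is bidirectional propagation from a
  well-behaved start slice (`direction = "both"`).
- `E_dev` regularizes across slices but also resists genuine abrupt area
  change; `delta` trades coherence against responsiveness.
- Frenet frames twist with the curve's torsion; in-plane twist is
  harmless for areas and volumes, and the minimal-twist lofting removes
  most of its effect on the mesh, but in-plane *orientation* between
  distant slices is not meaningful.
- The end segments of the centerline interpolate with one-sided tangents
  (see above); landmark placement should overshoot the region of interest.
- Mesh lofting assumes star-shaped-ish rings when capping with centroid
  fans; deeply concave end contours would need ear-clipping caps.

## A worked run

```{r example}
library(vtseg)
ph <- generate_phantom(phantom_spec(), seed = 0)   # reference arc phantom
stack <- anisotropic_diffusion(ph$stack, n_iter = 10, kappa = 10,
                               step = 1 / 7)
xs <- resample_cross_sections(stack, ph$spline, step_mm = 1.04,
                              size_px = 97, pixel_size_mm = 0.35)
cs <- segment_stack(xs, seed = c(48, 48))
af <- area_function(cs)
plot(af)
lines(ph$truth$positions, ph$truth$areas, lty = 2)
volume_between(af)                                  # ~12500 mm^3
```

The same pipeline is scriptable from a shell through `exec/vtseg`
(`phantom`, `preprocess`, `resample`, `segment`, `reconstruct`, `run`
subcommands over a YAML config); every run writes a manifest from which the
outputs can be reproduced byte for byte.
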